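#' Read a rooted Newick tree
#'
#' Wraps [ape::read.tree()] with strict validation: the file must contain a
#' single well-formed tree, and branch lengths must be present unless a
#' `default_length` is supplied to fill them in.
#'
#' @param path Newick file.
#' @param default_length optional branch length to assign when the file
#'   carries none.
#' @return a `phylo` tree.
#' @export
read_newick <- function(path, default_length = NULL) {
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(path)),
    error = function(e) NULL)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree in ", path)
    tr <- tr[[1L]]
  }
  if (is.null(tr$edge.length)) {
    if (is.null(default_length)) {
      stop("tree has no branch lengths (supply default_length to override)")
    }
    tr$edge.length <- rep(as.numeric(default_length), nrow(tr$edge))
  }
  tr
}

#' Write a tree in Newick format
#'
#' @param tree a `phylo` tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records tool version, the run configuration (including the seed), MD5
#' checksums of input files, and the produced output files, so a run can be
#' audited and tampered inputs detected.
#'
#' @param config named list describing the run; entries that are paths to
#'   existing files are checksummed as inputs.  A `seed` entry, when present,
#'   is surfaced at the top level.
#' @param outputs character vector of output file paths.
#' @param path manifest destination (JSON).
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(config, outputs, path) {
  checksum <- function(files) {
    files <- files[file.exists(files) & !dir.exists(files)]
    as.list(tools::md5sum(files))
  }
  input_paths <- as.character(unlist(Filter(function(x) {
    is.character(x) && length(x) == 1L && file.exists(x) && !dir.exists(x)
  }, config), use.names = FALSE))
  manifest <- list(
    tool = "eflratchet",
    version = as.character(utils::packageVersion("eflratchet")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    seed = config$seed,
    config = config,
    inputs = checksum(input_paths),
    outputs = checksum(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(manifest)
}
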