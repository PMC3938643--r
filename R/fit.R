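#' Estimate loss and HGT rates from tip states
#'
#' Maximum-likelihood estimation of the per-gene loss rate and the EFL HGT
#' rate of the ratchet process from presence/absence observations at the tips
#' of a tree.  The likelihood surface is first evaluated on a log-spaced grid
#' over the bounds, then refined from the best grid point with a
#' derivative-free Nelder-Mead search on the log scale.  The procedure is
#' deterministic given the settings.
#'
#' A single loss rate shared by the three genes is estimated; the fit assumes
#' one-step dynamics and the rejection lethality policy.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param tip_states observations in any form accepted by [tip_likelihood()].
#' @param bounds list with elements `loss` and `hgt`, each a positive
#'   length-2 range.
#' @param grid_n grid points per axis for the initial scan.
#' @param root_state root state of the process (default: all three genes).
#' @param control passed to [stats::optim()].
#' @return object of class `ratchet_fit` with components `estimates`
#'   (named vector `loss`, `hgt`), `logLik`, `grid` (the scanned surface),
#'   `degenerate` flag, `n_tips`, `bounds`, `convergence`.
#' @examples
#' tr <- make_tree(40, seed = 3)
#' m <- ratchet_model(loss_rate = 1, hgt_rate = 0.5,
#'                    root_state = c("eEF1A", "eEF1Ba", "EFL"))
#' h <- simulate(m, seed = 7, tree = tr)
#' fit <- fit_rates(tr, h$tip_states)
#' coef(fit)
#' @export
fit_rates <- function(tree, tip_states,
                      bounds = list(loss = c(1e-3, 20), hgt = c(1e-3, 20)),
                      grid_n = 7L,
                      root_state = c("eEF1A", "eEF1Ba", "EFL"),
                      control = list()) {
  check_tree(tree)
  stopifnot(all(bounds$loss > 0), all(bounds$hgt > 0),
            diff(bounds$loss) > 0, diff(bounds$hgt) > 0)
  ntip <- length(tree$tip.label)
  if (ntip < 10L) warning("fewer than 10 tips: rate estimates will be poor")

  ll_fun <- function(loss, hgt) {
    m <- ratchet_model(loss_rate = loss, hgt_rate = hgt,
                       root_state = root_state)
    tip_likelihood(m, tree, tip_states)
  }

  lg <- exp(seq(log(bounds$loss[1]), log(bounds$loss[2]), length.out = grid_n))
  hg <- exp(seq(log(bounds$hgt[1]), log(bounds$hgt[2]), length.out = grid_n))
  grid <- expand.grid(loss = lg, hgt = hg, KEEP.OUT.ATTRS = FALSE)
  grid$logLik <- mapply(ll_fun, grid$loss, grid$hgt)

  finite <- is.finite(grid$logLik)
  degenerate <- FALSE
  if (!any(finite) ||
      diff(range(grid$logLik[finite])) < 1e-8) {
    degenerate <- TRUE
    warning("flat likelihood surface: degenerate fit, returning grid only")
    best <- if (any(finite)) which.max(grid$logLik) else 1L
    est <- c(loss = grid$loss[best], hgt = grid$hgt[best])
    ll <- grid$logLik[best]
    conv <- NA_integer_
  } else {
    best <- which.max(grid$logLik)
    clamp <- function(lp) {
      c(min(max(lp[1], log(bounds$loss[1])), log(bounds$loss[2])),
        min(max(lp[2], log(bounds$hgt[1])), log(bounds$hgt[2])))
    }
    obj <- function(lp) {
      lp <- clamp(lp)
      ll <- ll_fun(exp(lp[1]), exp(lp[2]))
      if (!is.finite(ll)) 1e10 else -ll
    }
    opt <- optim(c(log(grid$loss[best]), log(grid$hgt[best])), obj,
                 method = "Nelder-Mead", control = control)
    lp <- clamp(opt$par)
    est <- c(loss = exp(lp[1]), hgt = exp(lp[2]))
    ll <- -opt$value
    conv <- opt$convergence
  }

  structure(
    list(estimates = est, logLik = ll, grid = grid, degenerate = degenerate,
         n_tips = ntip, bounds = bounds, convergence = conv,
         root_state = state_label(state_code(root_state))),
    class = "ratchet_fit")
}

#' @export
coef.ratchet_fit <- function(object, ...) object$estimates

#' @export
logLik.ratchet_fit <- function(object, ...) {
  structure(object$logLik, df = 2L, nobs = object$n_tips, class = "logLik")
}

#' @export
print.ratchet_fit <- function(x, ...) {
  cat("Ratchet rate fit (", x$n_tips, " tips, root ", x$root_state, ")\n",
      sep = "")
  cat(sprintf("  loss rate: %.4g\n  HGT rate:  %.4g\n  logLik:    %.4f\n",
              x$estimates["loss"], x$estimates["hgt"], x$logLik))
  if (x$degenerate) cat("  [degenerate: flat likelihood surface]\n")
  invisible(x)
}

#' @export
summary.ratchet_fit <- function(object, ...) {
  # profile each rate over the scanned grid
  prof_loss <- stats::aggregate(logLik ~ loss, object$grid, max)
  prof_hgt <- stats::aggregate(logLik ~ hgt, object$grid, max)
  out <- list(fit = object, profile_loss = prof_loss, profile_hgt = prof_hgt)
  class(out) <- "summary.ratchet_fit"
  out
}

#' @export
print.summary.ratchet_fit <- function(x, ...) {
  print(x$fit)
  cat("\nProfile over loss rate (grid):\n")
  print(x$profile_loss, row.names = FALSE)
  cat("\nProfile over HGT rate (grid):\n")
  print(x$profile_hgt, row.names = FALSE)
  invisible(x)
}

#' Plot the scanned likelihood surface of a ratchet fit
#'
#' @param x a `ratchet_fit`.
#' @param ... passed to [graphics::contour()].
#' @export
plot.ratchet_fit <- function(x, ...) {
  lg <- sort(unique(x$grid$loss)); hg <- sort(unique(x$grid$hgt))
  z <- matrix(x$grid$logLik[order(x$grid$hgt, x$grid$loss)],
              length(lg), length(hg))
  z[!is.finite(z)] <- min(z[is.finite(z)]) - 10
  graphics::contour(log10(lg), log10(hg), z,
                    xlab = "log10 loss rate", ylab = "log10 HGT rate", ...)
  graphics::points(log10(x$estimates["loss"]), log10(x$estimates["hgt"]),
                   pch = 19, col = "red")
  invisible(x)
}
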