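write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("a simple table parses to validated states", {
  path <- write_tsv_fixture(c(
    "taxon\teEF1A\teEF1Ba\tEFL",
    "t1\tpresent\tpresent\tpresent",
    "t2\tPresent\tpresent\tpresent",
    "t3\t1\t1\t1"))
  tab <- read_factor_table(path)
  expect_s3_class(tab, "factor_table")
  expect_equal(nrow(tab), 3L)
  expect_true(all(as.matrix(tab[, c("eEF1A", "eEF1Ba", "EFL")]) == "PRESENT"))
})

test_that("an EFL-only organism row parses with eEF1A and eEF1Ba absent", {
  path <- write_tsv_fixture(c(
    "taxon\teEF1A\teEF1Ba\tEFL",
    "Monosiga_brevicollis\tabsent\tabsent\tpresent"))
  tab <- read_factor_table(path)
  expect_equal(tab$eEF1A, "ABSENT")
  expect_equal(tab$eEF1Ba, "ABSENT")
  expect_equal(tab$EFL, "PRESENT")
})

test_that("bad tokens and duplicate taxa are rejected with location", {
  path <- write_tsv_fixture(c(
    "taxon\teEF1A\teEF1Ba\tEFL",
    "t1\tpresent\tmaybe\tabsent"))
  expect_error(read_factor_table(path), "maybe.*t1.*eEF1Ba")
  path2 <- write_tsv_fixture(c(
    "taxon\teEF1A\teEF1Ba\tEFL",
    "t1\tpresent\tpresent\tabsent",
    "t1\tpresent\tpresent\tabsent"))
  expect_error(read_factor_table(path2), "duplicate")
})

test_that("Greek and ASCII aliases of the GEF column header are accepted", {
  path <- write_tsv_fixture(c(
    "taxon\tlineage\teEF1A\teEF1Bα\tEFL",
    "t1\tFungi\tpresent\tdivergent\tabsent"))
  tab <- read_factor_table(path)
  expect_equal(tab$eEF1Ba, "DIVERGENT")
  expect_equal(tab$lineage, "Fungi")
})

test_that("binarize maps DIVERGENT by convention and ABSENT to FALSE always", {
  tab <- factor_table(c("a", "b", "c"),
                      eEF1A = c("present", "divergent", "absent"),
                      eEF1Ba = c("divergent", "absent", "present"),
                      EFL = c("absent", "present", "divergent"))
  bp <- binarize(tab, "divergent_as_present")
  ba <- binarize(tab, "divergent_as_absent")
  expect_true(bp["b", "eEF1A"])
  expect_false(ba["b", "eEF1A"])
  expect_false(bp["c", "eEF1A"]) # ABSENT under either convention
  expect_false(ba["c", "eEF1A"])
  expect_true(bp["c", "eEF1Ba"]) # PRESENT under either convention
  expect_true(ba["c", "eEF1Ba"])
  # monotone: divergent-as-present dominates divergent-as-absent
  expect_true(all(bp >= ba))
})

test_that("contingency enumerates mutually exclusive and uniform tables", {
  tab <- factor_table(c("efl_only", "canonical"),
                      eEF1A = c("absent", "present"),
                      eEF1Ba = c("absent", "present"),
                      EFL = c("present", "absent"))
  counts <- contingency(tab, "divergent_as_present", "EFL_vs_both")
  expect_equal(as.vector(counts), c(0L, 1L, 1L, 0L)) # column-major
  expect_equal(sum(counts), nrow(tab))

  tab4 <- factor_table(paste0("t", 1:4),
                       eEF1A = rep("absent", 4), eEF1Ba = rep("absent", 4),
                       EFL = rep("present", 4))
  counts4 <- contingency(tab4, "divergent_as_absent", "EFL_vs_both")
  expect_equal(counts4["EFL_present", "other_absent"], 4L)
  expect_equal(sum(counts4), 4L)
})

test_that("contingency on generator output equals planted tallies", {
  syn <- make_table(table_recipe(n_taxa = 50, mode = "ratchet_history",
                                 divergent_fraction = 0, seed = 71))
  pres <- syn$truth$presence
  counts <- contingency(syn$table, "divergent_as_present", "EFL_vs_eEF1A")
  expect_equal(counts["EFL_present", "other_present"],
               sum(pres[, "EFL"] & pres[, "eEF1A"]))
  expect_equal(counts["EFL_absent", "other_absent"],
               sum(!pres[, "EFL"] & !pres[, "eEF1A"]))
  expect_equal(sum(counts), 50L)
})

test_that("EFL+/other+ cell is monotone in the divergent convention", {
  set.seed(5)
  for (i in 1:20) {
    states <- matrix(sample(c("present", "divergent", "absent"), 3 * 15,
                            replace = TRUE), ncol = 3)
    tab <- factor_table(paste0("t", 1:15), states[, 1], states[, 2],
                        states[, 3])
    for (cmp in c("EFL_vs_both", "EFL_vs_eEF1A", "EFL_vs_eEF1Ba")) {
      cp <- contingency(tab, "divergent_as_present", cmp)
      ca <- contingency(tab, "divergent_as_absent", cmp)
      expect_gte(cp[1, 1], ca[1, 1])
    }
  }
})

test_that("association_report returns all six results and flags no-EFL tables", {
  tab <- factor_table(paste0("t", 1:6),
                      eEF1A = rep("present", 6), eEF1Ba = rep("present", 6),
                      EFL = rep("absent", 6))
  rep <- association_report(tab)
  expect_equal(nrow(rep), 6L)
  expect_setequal(unique(rep$comparison),
                  c("EFL_vs_both", "EFL_vs_eEF1A", "EFL_vs_eEF1Ba"))
  expect_true(all(rep$degenerate))
  expect_true(all(rep$p_two_sided == 1))
})

test_that("ratchet-generated tables with strong lineage sorting associate", {
  syn <- make_table(table_recipe(n_taxa = 60, mode = "ratchet_history",
                                 seed = 202))
  rep <- association_report(syn$table)
  expect_lt(min(rep$p_two_sided), 0.001)
})

test_that("lineage collapse yields one majority pseudo-taxon per lineage", {
  tab <- factor_table(c("a1", "a2", "a3", "b1", "solo"),
                      eEF1A = c("present", "present", "absent",
                                "absent", "present"),
                      eEF1Ba = c("absent", "absent", "absent",
                                 "present", "present"),
                      EFL = c("present", "present", "present",
                              "absent", "absent"),
                      lineage = c("A", "A", "A", "B", NA))
  col <- collapse_by_lineage(tab)
  expect_equal(nrow(col), 3L)
  a <- col[col$taxon == "A", ]
  expect_equal(a$eEF1A, "PRESENT")
  expect_equal(a$EFL, "PRESENT")
  expect_true("solo" %in% col$taxon)
})

test_that("factor tables round-trip through TSV", {
  tab <- factor_table(c("x", "y"), c("present", "divergent"),
                      c("absent", "present"), c("present", "absent"),
                      lineage = c("L1", "L2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_factor_table(tab, path)
  back <- read_factor_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})
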