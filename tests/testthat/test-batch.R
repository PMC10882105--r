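make_batch_dir <- function() {
  dir <- tempfile("batch")
  dir.create(dir)
  # two tCDA trials
  for (i in 1:2) {
    s <- synth_spec(hill_A = hill_params(10, 2), hill_B = hill_params(14, 1.6),
                    rho_true = c(0.2, -0.3)[i], n_units = 400,
                    time_grid = seq(0, 60, 0.05), seed = 80 + i)
    tr <- gen_trialset(s)
    write_survival_table(tr$arm_A, file.path(dir, paste0("t", i, "_a.csv")))
    write_survival_table(tr$arm_B, file.path(dir, paste0("t", i, "_b.csv")))
    write_survival_table(tr$arm_AB, file.path(dir, paste0("t", i, "_ab.csv")))
  }
  # two dCDA matrices
  for (i in 1:2) {
    s <- synth_spec(rho_true = c(0.3, 0)[i], n_units = 1e4,
                    noise_sd = 0.02, seed = 90 + i)
    write_dose_matrix(gen_combination_matrix(s),
                      file.path(dir, paste0("m", i, ".csv")))
  }
  manifest <- file.path(dir, "manifest.csv")
  writeLines(c(
    "combination_id,kind,path_a,path_b,path_ab,n_a,n_b,n_ab,path_matrix",
    paste0("trial1,tcda,t1_a.csv,t1_b.csv,t1_ab.csv,400,400,400,"),
    paste0("trial2,tcda,t2_a.csv,t2_b.csv,t2_ab.csv,400,400,400,"),
    "combo1,dcda,,,,,,,m1.csv",
    "combo2,dcda,,,,,,,m2.csv"), manifest)
  list(dir = dir, manifest = manifest)
}

test_that("batch runs fit every manifest row and are reproducible", {
  b <- make_batch_dir()
  cfg <- run_config(n_boot = 0, seed = 7)
  out_dir <- file.path(b$dir, "reports")
  s1 <- run_batch(b$manifest, cfg, out_dir = out_dir, quiet = TRUE)
  expect_equal(nrow(s1), 4L)
  expect_equal(s1$kind, c("tcda", "tcda", "dcda", "dcda"))
  # corrected threshold uses the per-kind batch size (m = 2 each)
  expect_equal(unique(s1$gof_threshold), 0.05 / 2)
  # recovered correlations near their generating values
  expect_lt(abs(s1$rho_hat[1] - 0.2), 0.15)
  expect_lt(abs(s1$rho_hat[3] - 0.3), 0.1)
  # per-combination reports on disk
  expect_true(all(file.exists(file.path(
    out_dir, paste0(s1$combination_id, ".json")))))
  # bit-identical rerun under the same seed
  s2 <- run_batch(b$manifest, cfg, quiet = TRUE)
  expect_identical(s1[setdiff(names(s1), "row.names")],
                   s2[setdiff(names(s2), "row.names")])
})

test_that("malformed rows are skipped, empty or all-bad manifests fail", {
  b <- make_batch_dir()
  # break one row's path: it is skipped, the rest still fit
  man2 <- file.path(b$dir, "manifest2.csv")
  lines <- readLines(b$manifest)
  lines[4] <- "combo1,dcda,,,,,,,missing.csv"
  writeLines(lines, man2)
  s <- suppressMessages(run_batch(man2, run_config(n_boot = 0, seed = 7)))
  expect_equal(nrow(s), 3L)
  expect_false("combo1" %in% s$combination_id)

  empty <- file.path(b$dir, "empty.csv")
  writeLines("combination_id,kind", empty)
  expect_error(run_batch(empty, run_config()), "empty manifest")

  allbad <- file.path(b$dir, "allbad.csv")
  writeLines(c("combination_id,kind,path_matrix",
               "x,dcda,nope.csv"), allbad)
  expect_error(suppressMessages(run_batch(allbad, run_config())),
               "all manifest rows failed")
})
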