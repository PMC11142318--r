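test_that("self-evaluation reproduces the metric identities", {
  cx <- make_toy_complex(seed = 30, templates = "acetate")
  r <- evaluate_primary(cx, cx, target_id = "self")
  expect_equal(r$status, "scored")
  expect_equal(r$rmsd, 0, tolerance = 1e-9)
  expect_equal(r$crmsd, 0, tolerance = 1e-9)
  expect_equal(r$lddt_pli, 1)
  expect_true(r$pb_valid)
  expect_equal(r$plif_emd, 0)
})

test_that("a 3 A translation scores rmsd 3 and misses the 2 A threshold", {
  cx <- make_toy_complex(seed = 31, templates = "benzene")
  pred <- perturb_pose(cx, "translate", magnitude = 3, seed = 8)
  r <- evaluate_primary(pred, cx)
  expect_equal(r$status, "scored")
  expect_equal(r$rmsd, 3, tolerance = 1e-8)
  expect_gt(r$rmsd, eval_config()$rmsd_success)
})

test_that("evaluation survives a prediction given in a different frame", {
  cx <- make_toy_complex(seed = 32, templates = "ethanol")
  pred <- perturb_pose(cx, "translate", magnitude = 1.2, seed = 9)
  set.seed(10)
  pred_moved <- apply_transform(pred, random_rigid())
  r <- evaluate_primary(pred_moved, cx)
  expect_equal(r$rmsd, 1.2, tolerance = 1e-7)
  expect_equal(r$crmsd, 1.2, tolerance = 1e-7)
})

test_that("a missing primary fragment excludes the prediction with a reason", {
  cx <- make_toy_complex(seed = 33, templates = "benzene")
  pred <- cx
  pred$ligands <- list(make_toy_ligand("ethanol"))
  pred$roles <- "primary"
  r <- evaluate_primary(pred, cx)
  expect_equal(r$status, "excluded")
  expect_match(r$reason, "primary")
  expect_true(is.na(r$rmsd))
})

test_that("multi-ligand protocol: identity, displaced fragment, swapped ions", {
  cx <- make_toy_complex(seed = 34,
                         templates = c("benzene", "ion", "acetate"))
  r <- evaluate_multi(cx, cx)
  frag_rows <- r[r$fragment != "complex", ]
  expect_equal(nrow(frag_rows), 3)
  expect_equal(max(abs(frag_rows$rmsd)), 0, tolerance = 1e-9)
  cplx <- r[r$fragment == "complex", ]
  expect_true(cplx$pb_valid)
  expect_equal(cplx$inter_ligand_clashes, 0L)
  # displace one fragment 5 A: exactly one failure at the 2 A threshold
  pred <- cx
  lig3 <- pred$ligands[[3]]
  pred$ligands[[3]] <- apply_transform(lig3,
                                       rigid_transform(diag(3), c(5, 0, 0)))
  r2 <- evaluate_multi(pred, cx)
  fr2 <- r2[r2$fragment != "complex", ]
  expect_equal(sum(fr2$rmsd <= 2), 2)
  expect_equal(sum(fr2$rmsd > 2), 1)
  # two identical ions with crossed labels both score zero
  ion <- make_toy_ligand("ion")
  base <- make_toy_complex(seed = 35, templates = c("benzene", "ion"))
  ion1 <- poseval:::set_ligand_coords(ion, matrix(c(4, 0, 0), 1))
  ion2 <- poseval:::set_ligand_coords(ion, matrix(c(-4, 0, 0), 1))
  ref <- complex_pose(base$protein, list(ion1, ion2),
                      c("primary", "fragment"))
  swapped <- complex_pose(base$protein, list(ion2, ion1),
                          c("primary", "fragment"))
  r3 <- evaluate_multi(swapped, ref)
  fr3 <- r3[r3$fragment != "complex", ]
  expect_equal(max(abs(fr3$rmsd)), 0, tolerance = 1e-9)
})

test_that("unmatched reference fragments are unsuccessful rows, not errors", {
  cx <- make_toy_complex(seed = 36, templates = c("benzene", "ion"))
  pred <- cx
  pred$ligands <- pred$ligands[1]
  pred$roles <- "primary"
  r <- evaluate_multi(pred, cx)
  fr <- r[r$fragment != "complex", ]
  expect_equal(sum(fr$status == "excluded"), 1)
  expect_equal(sum(fr$status == "scored"), 1)
})

test_that("aggregation uses the full denominator and sample sd across runs", {
  # 10 targets: 4 scored successes, 5 scored failures, 1 excluded -> 40%
  rows <- dplyr::bind_rows(
    lapply(1:4, function(i) poseval:::result_row(paste0("t", i), rmsd = 1,
                                                 crmsd = 0.5,
                                                 pb_valid = TRUE,
                                                 plif_emd = 0.1)),
    lapply(5:9, function(i) poseval:::result_row(paste0("t", i), rmsd = 6,
                                                 crmsd = 5, pb_valid = TRUE,
                                                 plif_emd = 0.9)),
    list(poseval:::result_row("t10", status = "excluded",
                              reason = "missing")))
  rows$method <- "A"; rows$run <- 1
  s <- suppressWarnings(aggregate_runs(rows))  # one-method collection
  expect_equal(s$rate_rmsd, 40)
  expect_equal(s$rate_centroid, 40)
  expect_equal(s$rate_rmsd_pbvalid, 40)
  expect_equal(s$n_targets, 10)
  # three runs at 40/50/60%: mean 50, sample sd 10
  mk_run <- function(run, k) {
    r <- dplyr::bind_rows(
      lapply(seq_len(k), function(i)
        poseval:::result_row(paste0("t", i), rmsd = 1, crmsd = 0.5,
                             pb_valid = TRUE, plif_emd = 0.2)),
      lapply(seq_len(10 - k), function(i)
        poseval:::result_row(paste0("u", i), rmsd = 8, crmsd = 6,
                             pb_valid = TRUE, plif_emd = 0.2)))
    r$method <- "A"; r$run <- run
    r
  }
  runs <- dplyr::bind_rows(mk_run(1, 4), mk_run(2, 5), mk_run(3, 6))
  s3 <- suppressWarnings(aggregate_runs(runs))
  expect_equal(s3$rate_rmsd, 50)
  expect_equal(s3$rate_rmsd_sd, 10)
  expect_equal(s3$n_runs, 3)
})

test_that("accuracy-and-validity rate never exceeds the accuracy rate", {
  set.seed(44)
  rows <- dplyr::bind_rows(lapply(1:12, function(i)
    poseval:::result_row(paste0("t", i), rmsd = runif(1, 0, 4),
                         crmsd = runif(1, 0, 2),
                         pb_valid = runif(1) < 0.5, plif_emd = runif(1))))
  rows$method <- "A"; rows$run <- 1
  s <- suppressWarnings(aggregate_runs(rows))
  expect_lte(s$rate_rmsd_pbvalid, s$rate_rmsd)
})

test_that("a single-method collection gets PLIF-WM 1 with a warning", {
  rows <- poseval:::result_row("t1", rmsd = 1, crmsd = 1, pb_valid = TRUE,
                               plif_emd = 0.4)
  rows$method <- "only"; rows$run <- 1
  expect_warning(s <- aggregate_runs(rows), "degenerate")
  expect_equal(s$plif_wm, 1)
})

test_that("batch evaluation round-trips through files and the manifest", {
  dir <- withr::local_tempdir()
  profiles <- list(list(name = "good", success_fraction = 1, noise = 0),
                   list(name = "poor", success_fraction = 0, noise = 0))
  manifest <- make_benchmark(21, 3, profiles, dir)
  res <- evaluate_batch(file.path(dir, "manifest.csv"), base_dir = dir,
                        quiet = TRUE)
  expect_equal(nrow(res), 6)
  expect_true(all(res$status == "scored"))
  s <- aggregate_runs(res)
  expect_equal(s$rate_rmsd[s$method == "good"], 100)
  expect_equal(s$rate_rmsd[s$method == "poor"], 0)
  expect_gt(s$plif_wm[s$method == "good"], s$plif_wm[s$method == "poor"])
})
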