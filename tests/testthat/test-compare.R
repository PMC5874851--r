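## pipeline tests run on a reduced scenario set with a small Monte Carlo so
## the heavy full-grid run lives only in the acceptance suite

small_scenarios <- function() {
  sc <- paper_scenarios()
  sc[sc$scenario %in% c("E160_RS36.5", "E160_RS17.5", "E160_open"), ]
}

comparison_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- commissioning_fixture()
      cache <<- run_comparison(small_scenarios(), fx$dataset, fx$rs,
                               n_protons = 50000, seed = 4)
    }
    cache
  }
})

test_that("open-beam scenarios: all three methods agree", {
  tab <- comparison_fixture()
  op <- tab[tab$role == "open", ]
  expect_gt(nrow(op), 0)
  ## V route equals FE exactly for the open beam (same fitted moments)
  expect_lt(max(abs(op$diff_v_fe_mm)), 1e-9)
  ## MC within statistical tolerance
  expect_true(all(abs(op$diff_mc_fe_mm) < pmax(0.02, 4 * op$sigma_mc_se_mm)))
})

test_that("with-RS scenarios carry consistent diffs and positive SEs", {
  tab <- comparison_fixture()
  expect_true(all(tab$sigma_mc_se_mm > 0))
  expect_equal(tab$diff_v_fe_mm, tab$sigma_v_mm - tab$sigma_fe_mm)
  expect_equal(tab$rel_v_fe_pct,
               100 * tab$diff_v_fe_mm / tab$sigma_fe_mm)
  rs_rows <- tab[tab$role == "with_rs", ]
  expect_true(all(rs_rows$sigma_fe_mm > 0))
  ## commissioned per-energy V at the commissioning position: within the
  ## few-percent equation spread
  at_ref <- rs_rows[rs_rows$rs_face_cm == 36.5, ]
  expect_lt(max(abs(at_ref$rel_v_fe_pct)), 5)
})

test_that("the pipeline is deterministic and its summary recomputable", {
  fx <- commissioning_fixture()
  t1 <- run_comparison(small_scenarios()[1, ], fx$dataset, fx$rs,
                       n_protons = 20000, seed = 11)
  t2 <- run_comparison(small_scenarios()[1, ], fx$dataset, fx$rs,
                       n_protons = 20000, seed = 11)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  render_report(t1, d1, formats = c("csv", "json"))
  render_report(t2, d2, formats = c("csv", "json"))
  expect_identical(readBin(file.path(d1, "comparison.csv"), "raw", 1e6),
                   readBin(file.path(d2, "comparison.csv"), "raw", 1e6))
  expect_identical(readBin(file.path(d1, "summary.json"), "raw", 1e7),
                   readBin(file.path(d2, "summary.json"), "raw", 1e7))
  ## summary statistics recompute from the CSV
  csv <- utils::read.csv(file.path(d1, "comparison.csv"))
  summ <- read_comparison_summary(file.path(d1, "summary.json"))
  expect_equal(summ$max_abs_rel_v_fe_pct, max(abs(csv$rel_v_fe_pct)),
               tolerance = 1e-12)
  ## the JSON summary round-trips the full table
  expect_equal(summ$table$sigma_fe_mm, t1$sigma_fe_mm, tolerance = 1e-12)
})

test_that("reports render files for every scenario", {
  tab <- comparison_fixture()
  dir <- file.path(tempdir(), "report_full")
  files <- render_report(tab, dir)
  expect_true(all(file.exists(files)))
  expect_true(all(file.size(files) > 0))
  pngs <- grep("\\.png$", files, value = TRUE)
  expect_length(pngs, length(unique(tab$scenario)))
})

test_that("clamp emulation inflates the V-route spots above the crossing energy", {
  fx <- commissioning_fixture()
  sc <- paper_scenarios()
  sc <- sc[sc$scenario %in% c("E226.7_RS26.5", "E140_RS26.5"), ]
  tab <- run_comparison(sc, fx$dataset, fx$rs, n_protons = 0,
                        emulate_clamp = TRUE)
  hi <- tab[tab$energy_MeV == 226.7, ]
  lo <- tab[tab$energy_MeV == 140, ]
  expect_true(all(hi$clamped))
  expect_false(any(lo$clamped))
  ## frozen low-energy moments make the predicted spot too large at isocenter
  expect_true(all(hi$diff_v_fe_mm[hi$z_cm == 0] > 0))
  ## low energies untouched relative to the plain pipeline
  plain <- run_comparison(sc[sc$energy_MeV == 140, ], fx$dataset, fx$rs,
                          n_protons = 0)
  expect_equal(lo$sigma_v_mm, plain$sigma_v_mm, tolerance = 1e-12)
})

test_that("missing commissioning energies raise a configuration error", {
  fx <- commissioning_fixture()
  sub <- fx$dataset[fx$dataset$energy_MeV != 105, ]
  class(sub) <- class(fx$dataset)
  sc <- paper_scenarios()[1, ]                  # a 105 MeV scenario
  expect_error(run_comparison(sc, sub, fx$rs, n_protons = 0),
               "configuration error.*105")
})
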