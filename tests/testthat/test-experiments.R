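test_that("selection-pressure sweep tabulates exact and analytic curves", {
  sw <- sweep_selection_pressure(Ni = 45, Nf = 50, Ns_grid = c(0, 0.2, 1))
  n_interior <- nrow(enumerate_states(model_params(45, 50)))
  expect_equal(nrow(sw), 3 * n_interior)
  expect_setequal(names(sw),
                  c("Nf_s_bar", "s_bar", "m", "n", "mu", "eta",
                    "pi_exact", "pi_analytic", "abs_dev"))
  ## neutral row: exact and analytic coincide
  expect_lt(max(sw$abs_dev[sw$Nf_s_bar == 0]), 1e-9)
  dev <- attr(sw, "deviations")
  expect_equal(dev$Nf_s_bar, c(0, 0.2, 1))
  ## deviations grow with the selection pressure
  expect_true(all(diff(dev$max_abs_dev) > 0))
})

test_that("numerical crossing agrees with the leading-order criterion", {
  cr <- scan_crossing(pairs = cbind(Ni = 90, Nf = 100))
  expect_equal(cr$Ns_star_theory, 10 / 95)
  expect_lt(abs(cr$Ns_star - 10 / 95), 2 / 95)
  expect_equal(cr$scaled_gap, 95 * (cr$Ns_star - 10 / 95))
  ## the crossing satisfies pi_A = pi_S to bisection accuracy
  ft <- solve_fixation(model_params(90, 100, 1 + cr$s_bar_star))
  expect_lt(abs(ft$pi_A - ft$pi_S), 1e-7)
})

test_that("result tables round-trip with their provenance header", {
  p <- model_params(45, 50, 1.01, alpha = 2)
  df <- data.frame(m = c(44, 1), n = c(1, 49), pi = c(0.02, 0.97))
  path <- tempfile(fileext = ".tsv")
  write_table_tsv(df, path, params = p, extra = list(seed = 7))
  back <- read_table_tsv(path)
  expect_equal(back$pi, df$pi)
  hdr <- attr(back, "header")
  expect_equal(hdr[["Ni"]], 45)
  expect_equal(hdr[["cost"]], 1.01)
  expect_equal(hdr[["alpha"]], 2)
  expect_equal(hdr[["seed"]], 7)
})

test_that("cli solve emits the solver's numbers as JSON", {
  out <- tempfile(fileext = ".json")
  tab <- tempfile(fileext = ".tsv")
  status <- cli_main(c("solve", "--Ni", "45", "--Nf", "50", "--c", "1.001",
                       "--out", out, "--table", tab))
  expect_equal(status, 0L)
  res <- jsonlite::fromJSON(out)
  ft <- solve_fixation(model_params(45, 50, 1.001))
  expect_equal(res$pi_A, ft$pi_A, tolerance = 1e-12)
  expect_equal(res$pi_S, ft$pi_S, tolerance = 1e-12)
  expect_equal(res$params$Ni, 45)
  tabin <- read_table_tsv(tab)
  expect_equal(nrow(tabin), nrow(ft$table))
})

test_that("cli simulate is seed-deterministic", {
  o1 <- tempfile(); o2 <- tempfile()
  args <- c("simulate", "--Ni", "10", "--Nf", "14", "--c", "1.01",
            "--m0", "9", "--n0", "1", "--R", "2000", "--seed", "5")
  expect_equal(cli_main(c(args, "--out", o1)), 0L)
  expect_equal(cli_main(c(args, "--out", o2)), 0L)
  expect_identical(readLines(o1), readLines(o2))
  res <- jsonlite::fromJSON(o1)
  expect_equal(res$R, 2000)
  expect_equal(res$seed, 5)
})

test_that("cli reads config files and rejects bad input", {
  cfg <- tempfile()
  writeLines(c("Ni = 45", "Nf = 50", "c = 1.002"), cfg)
  out <- tempfile()
  expect_equal(cli_main(c("solve", "--config", cfg, "--out", out)), 0L)
  res <- jsonlite::fromJSON(out)
  expect_equal(res$params$cost, 1.002)
  ## option overrides config
  expect_equal(cli_main(c("solve", "--config", cfg, "--c", "1.5",
                          "--out", out)), 0L)
  expect_equal(jsonlite::fromJSON(out)$params$cost, 1.5)

  expect_equal(suppressMessages(cli_main(c("nonsense"))), 1L)
  expect_equal(suppressMessages(cli_main(c("solve", "--Ni", "50",
                                           "--Nf", "45"))), 1L)
})

test_that("cli structured and meanfield produce well-formed output", {
  out <- tempfile()
  expect_equal(cli_main(c("structured", "--Ni", "45", "--Nf", "50",
                          "--c", "1.0005", "--M", "8", "--out", out)), 0L)
  res <- jsonlite::fromJSON(out)
  expect_true(all(c("r", "Pi_A", "Pi_S") %in% names(res)))
  tsv <- tempfile(fileext = ".tsv")
  expect_equal(cli_main(c("meanfield", "--Ni", "90", "--Nf", "100",
                          "--c", "1.01", "--mu0", "0.5", "--eta0", "0.95",
                          "--tau-end", "100", "--out", tsv)), 0L)
  tr <- read_table_tsv(tsv)
  expect_equal(names(tr), c("tau", "mu", "eta"))
  expect_true(all(diff(tr$mu) <= 0))
})
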