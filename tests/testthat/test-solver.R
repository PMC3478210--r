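test_that("anti-diagonal indexing is the documented closed form and a bijection", {
  p <- model_params(5, 8)
  expect_equal(state_to_index(4, 1, p), 1L)
  expect_equal(state_to_index(1, 4, p), 4L)
  expect_equal(state_to_index(5, 1, p), 5L)  # first state of the delta = 1 line

  st <- enumerate_states(p)
  expect_equal(st$k, seq_len(nrow(st)))
  expect_equal(state_to_index(st$m, st$n, p), st$k)
  ## line sizes: Ni - 1 + delta states on line delta
  expect_equal(as.numeric(table(st$delta)), 4:7)
  expect_error(state_to_index(0, 5, p), "interior")
})

test_that("the assembled system has the conservation stencil structure", {
  p <- model_params(8, 14, 1.2)
  sys <- build_linear_system(p)
  K <- nrow(sys$states)
  expect_equal(dim(sys$W), c(K, K))
  ## row-equilibrated: unit diagonal; at most 4 off-diagonal neighbors
  expect_equal(Matrix::diag(sys$W), rep(1, K))
  nnz_per_row <- Matrix::rowSums(sys$W != 0)
  expect_true(all(nnz_per_row <= 5))
  ## unscaled diagonal is the total exit rate of the four channels
  r <- transition_rates(sys$states$m, sys$states$n, p)
  expect_equal(sys$diag, r$birth_S + r$birth_A + r$death_S + r$death_A)
  ## conservation: off-diagonal mass + boundary flux accounts for the diagonal
  offdiag <- Matrix::rowSums(abs(sys$W)) - 1
  bd_A <- sys$B                                     # flux into m = 0
  r_dA <- r$death_A / sys$diag                      # flux into n = 0
  flux_S <- ifelse(sys$states$n == 1, r_dA, 0)
  expect_equal(offdiag + bd_A + flux_S, rep(1, K), tolerance = 1e-12)
})

test_that("the three-state instance matches a hand-assembled solve", {
  ## Ni = 2, Nf = 3, cost = 2: interior = {(1,1), (2,1), (1,2)}
  cost <- 2
  ## rates at (1,1): bS = 1/2, bA = 1/2 (no deaths at N = Ni)
  ## rates at (2,1): dS = 4/3, dA = 2*2/3 (no births at N = Nf)
  ## rates at (1,2): dS = 1/3, dA = 2*2/3
  A <- rbind(
    c(1, -1 / 2, -1 / 2),          # (1,1): (bS+bA) pi1 - bS pi2 - bA pi3 = 0
    c(-4 / 3, 4 / 3 + 4 / 3, 0),   # (2,1): dS -> (1,1); dA -> (2,0), pi = 0
    c(-4 / 3, 0, 1 / 3 + 4 / 3)    # (1,2): dA -> (1,1); dS -> (0,2), pi = 1
  )
  b <- c(0, 0, 1 / 3)
  by_hand <- solve(A, b)

  ft <- solve_fixation(model_params(2, 3, cost))
  tb <- ft$table
  expect_equal(tb$pi[tb$m == 1 & tb$n == 1], by_hand[1])
  expect_equal(tb$pi[tb$m == 2 & tb$n == 1], by_hand[2])
  expect_equal(tb$pi[tb$m == 1 & tb$n == 2], by_hand[3])
  expect_equal(ft$pi_A, by_hand[1])   # single altruist: (m, n) = (Ni - 1, 1)
  expect_equal(ft$pi_S, 1 - by_hand[3])
})

test_that("neutral fixation probability is the altruist proportion", {
  ft <- solve_fixation(model_params(15, 20, cost = 1))
  expect_lt(max(abs(ft$table$pi - ft$table$n / (ft$table$m + ft$table$n))),
            1e-9)
  expect_equal(ft$pi_A, 1 / 15, tolerance = 1e-9)
  expect_equal(ft$pi_S, 1 / 20, tolerance = 1e-9)
})

test_that("sparse solve agrees with the dense fundamental-matrix oracle", {
  for (cost in c(1, 1.3)) {
    for (Nf in c(5, 9, 12)) {
      for (Ni in seq(2, Nf - 1)) {
        ft <- solve_fixation(model_params(Ni, Nf, cost))
        or <- oracle_fixation_dense(Ni, Nf, cost)
        merged <- merge(ft$table, or, by = c("m", "n"),
                        suffixes = c("_sparse", "_dense"))
        expect_lt(max(abs(merged$pi_sparse - merged$pi_dense)), 1e-10)
      }
    }
  }
})

test_that("fixation probabilities do not depend on the event-rate scale", {
  base <- solve_fixation(model_params(10, 16, 1.1, alpha = 1))
  for (a in c(0.1, 10)) {
    ft <- solve_fixation(model_params(10, 16, 1.1, alpha = a))
    expect_equal(ft$table$pi, base$table$pi, tolerance = 1e-12)
  }
})

test_that("pi is monotone in the state and in the cost", {
  ft <- solve_fixation(model_params(10, 16, 1.05))
  tb <- ft$table
  for (d in unique(tb$delta)) {
    line <- tb[tb$delta == d, ]
    line <- line[order(line$n), ]
    expect_true(all(diff(line$pi) > 0))
  }
  costs <- c(1, 1.02, 1.05, 1.1)
  piA <- vapply(costs, function(co) solve_fixation(model_params(10, 16, co))$pi_A, 0)
  piS <- vapply(costs, function(co) solve_fixation(model_params(10, 16, co))$pi_S, 0)
  ## costlier altruism hurts the altruist mutant and helps the selfish one
  expect_true(all(diff(piA) < 0))
  expect_true(all(diff(piS) > 0))
})

test_that("pi_A - pi_S crosses zero exactly once as the cost grows", {
  Ni <- 20; Nf <- 24
  sb <- seq(0, 0.05, length.out = 26)
  gap <- vapply(sb, function(s) {
    ft <- solve_fixation(model_params(Ni, Nf, 1 + s))
    ft$pi_A - ft$pi_S
  }, 0)
  expect_gt(gap[1], 0)                      # 1/Ni > 1/Nf at s_bar = 0
  expect_lt(gap[length(gap)], 0)
  expect_equal(sum(diff(sign(gap)) != 0), 1)
})

test_that("Moran-limit solve reproduces the classical closed form", {
  for (cost in c(1.02, 1.05)) {
    mr <- solve_fixation_moran(model_params(50, 51, cost))
    expect_lt(max(abs(mr$pi - moran_fixation_exact(mr$n, 50, cost))), 1e-8)
  }
  mr1 <- solve_fixation_moran(model_params(30, 31, cost = 1))
  expect_equal(mr1$pi, mr1$n / 30, tolerance = 1e-10)
  expect_error(solve_fixation_moran(model_params(30, 40)), "Nf = Ni \\+ 1")
})
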