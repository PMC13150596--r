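# brute-force orthogonal-projection oracle for one SPA step: residual norm
# of every column after projecting out the span of the chosen columns
spa_step_oracle <- function(x, chosen) {
  Q <- qr.Q(qr(x[, chosen, drop = FALSE]))
  resid <- x - Q %*% crossprod(Q, x)
  rn <- sqrt(colSums(resid^2))
  rn[chosen] <- -Inf
  which.max(rn)
}

test_that("spa_chain picks orthogonal columns and skips collinear ones", {
  e <- diag(4)[, 1:2]
  expect_equal(spa_chain(e, start = 1, m = 2), c(1L, 2L))
  v <- c(1, 2, 3, 4); w <- c(-2, 1, 0, 0)  # w orthogonal to v
  x <- cbind(v, 2 * v, w)
  expect_equal(spa_chain(x, start = 1, m = 2), c(1L, 3L))
  expect_error(spa_chain(x, start = 1, m = 3), "rank exhausted")
  expect_equal(spa_chain(x, start = 1, m = 3, partial = TRUE), c(1L, 3L))
})

test_that("spa_chain equals the per-step projection oracle on random matrices", {
  set.seed(51)
  for (rep in 1:5) {
    x <- matrix(rnorm(30), 6, 5)
    for (start in 1:5) {
      for (m in 2:3) {
        chain <- spa_chain(x, start, m)
        expect_equal(chain[1], start)
        for (s in 2:m) {
          expect_equal(chain[s],
                       unname(spa_step_oracle(x, chain[seq_len(s - 1)])))
        }
      }
    }
  }
})

test_that("spa_select recovers a single perfectly separating column at cost 0", {
  ps <- perfectly_separable()
  sel <- spa_select(ps$x, spa_config(max_vars = 3), classes = ps$classes)
  expect_equal(sel$selected_indices, ps$sep_col)
  expect_equal(sel$cost, 0)
  expect_equal(sel$size, 1L)
  # cost always reproduces on re-evaluation of the selected subset
  expect_equal(sel$cost,
               loo_cost(ps$x[, sel$selected_indices, drop = FALSE],
                        ps$classes))
})

test_that("spa_select null case falls back to the parsimony tie rule", {
  # both classes identical in every column: no subset beats chance and all
  # costs tie, so the parsimony rule returns m = 1, start = 1
  x <- matrix(rep(c(1, 2, 5, 7, 1, 2, 5, 7), 4), 8, 4)
  classes <- rep(c("A", "B"), each = 4)
  single_costs <- sapply(1:4, function(j) {
    loo_cost(x[, j, drop = FALSE], classes)
  })
  expect_length(unique(single_costs), 1L)
  sel <- spa_select(x, spa_config(max_vars = 2), classes = classes)
  expect_equal(sel$size, 1L)
  expect_equal(sel$start, 1L)
  expect_gte(sel$cost, 0.5)  # never better than the class prior
})

test_that("spa_select regret vs exhaustive subset search is bounded", {
  set.seed(52)
  x <- matrix(rnorm(20 * 8), 20, 8)
  x[, 5] <- x[, 5] + rep(c(-1.2, 1.2), each = 10)
  classes <- rep(c("A", "B"), each = 10)
  best <- Inf
  for (m in 1:3) {
    combs <- utils::combn(8, m)
    for (j in seq_len(ncol(combs))) {
      best <- min(best, loo_cost(x[, combs[, j], drop = FALSE], classes))
    }
  }
  sel <- spa_select(x, spa_config(max_vars = 3), classes = classes)
  expect_lte(sel$cost - best, 0.1)
  # exact agreement when a single column attains cost 0
  ps <- perfectly_separable(seed = 6)
  sel0 <- spa_select(ps$x, spa_config(max_vars = 3), classes = ps$classes)
  expect_equal(sel0$cost, 0)
})

test_that("ga_select finds a perfectly separating column and respects the cap", {
  ps <- perfectly_separable(n_a = 8, n_b = 8, p = 12, sep_col = 7, seed = 8)
  sel <- ga_select(ps$x, ga_config(population = 20, generations = 20,
                                   seed = 5), classes = ps$classes)
  expect_equal(sel$cost, 0)
  expect_true(ps$sep_col %in% sel$selected_indices)
  expect_lte(length(sel$selected_indices), 10)
  # elitism: best-ever cost trace is non-increasing
  expect_true(all(diff(sel$trace) <= 0))
  # deterministic given seed
  sel2 <- ga_select(ps$x, ga_config(population = 20, generations = 20,
                                    seed = 5), classes = ps$classes)
  expect_identical(sel$selected_indices, sel2$selected_indices)
  expect_identical(sel$trace, sel2$trace)
  sel3 <- ga_select(ps$x, ga_config(population = 20, generations = 5,
                                    seed = 6, max_vars = 2),
                    classes = ps$classes)
  expect_lte(length(sel3$selected_indices), 2)
})

test_that("fisher weights follow the two-class formula and attribution", {
  x <- rbind(matrix(c(0, 1, 2), 3, 1), matrix(c(2, 3, 4), 3, 1))
  classes <- rep(c("A", "B"), each = 3)
  fw <- fisher_weights(x, 1, classes = classes)
  expect_equal(fw$weight, (1 - 3)^2 / (1 + 1))  # = 2
  expect_equal(fw$attributed_class, "B")
  # identical class distributions -> weight 0
  x2 <- cbind(rep(c(0, 1, 2), 2))
  fw2 <- fisher_weights(x2, 1, classes = classes)
  expect_equal(fw2$weight, 0)
  # zero pooled variance -> infinite-weight flag, no error
  x3 <- cbind(rep(c(0, 0, 0, 1, 1, 1)))
  fw3 <- fisher_weights(x3, 1, classes = classes)
  expect_true(fw3$infinite)
  expect_equal(fw3$attributed_class, "B")
})

test_that("the largest Fisher weight among selected variables sits on a planted marker", {
  fix <- uv_samples(seed = 13, normalize = "none")
  part <- supervised_partition(fix$samples)
  sel <- spa_select(part$train)
  fw <- fisher_weights(part$train, sel$selected_indices)
  top <- fw$index[which.max(fw$weight)]
  markers <- c(fix$ground_truth$marker_indices_a,
               fix$ground_truth$marker_indices_b)
  # within the band support (2 sigma = 8 grid steps for the default bands)
  expect_lte(min(abs(top - markers)), 8)
})

test_that("both selection methods recover planted markers within the band support", {
  # recovery is assessed on the chain without min-max normalization, which
  # keeps class information localized at the planted bands. SPA's parsimony
  # rule stays on the band core (2 sigma); GA's multi-variable chromosomes
  # can ride a band's tail farther out, so its radius is the full tail
  # support (4 sigma)
  markers_nm <- c(259, 284, 356)
  sigma <- 4  # default UV marker width
  spa_hits <- ga_hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    fix <- uv_samples(seed = 300 + s, normalize = "none")
    part <- supervised_partition(fix$samples)
    mindist <- function(sel) {
      min(abs(outer(part$train$axis[sel$selected_indices], markers_nm, "-")))
    }
    spa_hits <- spa_hits + (mindist(spa_select(part$train)) <= 2 * sigma)
    ga <- ga_select(part$train, ga_config(population = 50, generations = 40,
                                          seed = s))
    ga_hits <- ga_hits + (mindist(ga) <= 4 * sigma)
  }
  expect_gte(spa_hits / n_seeds, 0.95)
  expect_gte(ga_hits / n_seeds, 0.95)
})
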