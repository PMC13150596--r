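#' SPA search configuration
#'
#' @param max_vars largest candidate subset size (default 10, the cap used
#'   throughout this workflow).
#' @param candidate_sizes subset sizes ("selection windows") to evaluate;
#'   default `1:max_vars`.
#' @return an `spa_config` object.
#' @export
spa_config <- function(max_vars = 10L, candidate_sizes = seq_len(max_vars)) {
  stopifnot(max_vars >= 1L, all(candidate_sizes >= 1L),
            all(candidate_sizes <= max_vars))
  structure(list(max_vars = as.integer(max_vars),
                 candidate_sizes = as.integer(candidate_sizes)),
            class = "spa_config")
}

#' GA search configuration
#'
#' Defaults are the standard settings of this workflow: 5% per-gene
#' mutation, 60% crossover, at most 10 variables per chromosome, elitism 1.
#'
#' @param population population size (>= 2).
#' @param generations number of generations.
#' @param mutation_rate per-gene replacement probability.
#' @param crossover_rate probability a selected pair recombines.
#' @param max_vars maximum chromosome length (distinct variable indices).
#' @param elitism number of best chromosomes copied unchanged (>= 1 keeps
#'   the best-ever fitness monotone).
#' @param seed integer RNG seed; runs are deterministic given the seed.
#' @return a `ga_config` object.
#' @export
ga_config <- function(population = 100L, generations = 100L,
                      mutation_rate = 0.05, crossover_rate = 0.60,
                      max_vars = 10L, elitism = 1L, seed = 1L) {
  stopifnot(population >= 2L, generations >= 1L,
            mutation_rate >= 0, mutation_rate <= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            max_vars >= 1L, elitism >= 0L)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 max_vars = as.integer(max_vars),
                 elitism = as.integer(elitism), seed = as.integer(seed)),
            class = "ga_config")
}

#' Successive projections chain
#'
#' Forward chain of minimally collinear columns: starting from `start`, each
#' step appends the column whose projection onto the orthogonal complement
#' of the span of the already-chosen columns has maximal norm (ties:
#' smallest index). Columns whose residual norm falls below `tol` times the
#' largest column norm are ineligible (numerically inside the span).
#'
#' @param x numeric matrix (columns are candidate variables).
#' @param start 1-based index of the first column of the chain.
#' @param m chain length, `1 <= m <= min(n - 1, p)`.
#' @param tol relative residual-norm tolerance for eligibility.
#' @param partial if `TRUE`, a rank-exhausted chain is returned as-is
#'   (shorter than `m`) instead of raising an error.
#' @return integer vector of `m` column indices in chain order.
#' @export
spa_chain <- function(x, start, m, tol = 1e-9, partial = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  stopifnot(start >= 1L, start <= p)
  if (m < 1L || m > min(n - 1L, p)) {
    stop(sprintf("chain length m must lie in [1, %d]", min(n - 1L, p)),
         call. = FALSE)
  }
  norm0 <- sqrt(colSums(x^2))
  thresh <- tol * max(norm0, 1e-300)
  R <- x                      # residuals of every column w.r.t. the chain
  chain <- integer(m)
  chain[1] <- as.integer(start)
  for (step in seq_len(m)) {
    if (step > 1L) {
      rn <- sqrt(colSums(R^2))
      rn[chain[seq_len(step - 1L)]] <- -Inf
      rn[rn < thresh] <- -Inf
      if (!any(is.finite(rn))) {
        if (partial) return(chain[seq_len(step - 1L)])
        stop(sprintf(
          "rank exhausted after %d variables (attained chain: %s)",
          step - 1L, paste(chain[seq_len(step - 1L)], collapse = ", ")),
          call. = FALSE)
      }
      chain[step] <- which.max(rn)  # smallest index among exact ties
    }
    q <- R[, chain[step]]
    qn <- sqrt(sum(q^2))
    if (qn < thresh) {
      if (partial) return(chain[seq_len(step - 1L)])
      stop(sprintf("start column %d is numerically zero", chain[step]),
           call. = FALSE)
    }
    q <- q / qn
    R <- R - outer(q, drop(crossprod(R, q)))
  }
  chain
}

#' SPA-LDA variable selection
#'
#' For every possible start column and every candidate subset size, builds
#' the successive-projections chain and scores its leave-one-out LDA
#' misclassification on the training partition; returns the minimum-cost
#' subset. Ties are broken toward the smaller subset size, then the smaller
#' start index (parsimony first). Fully deterministic.
#'
#' @param train a two-class [spectral_dataset] partition, or a matrix with
#'   `classes` supplied.
#' @param cfg an [spa_config()].
#' @param classes per-row labels when `train` is a matrix.
#' @return list of class `selection_result`: `selected_indices` (sorted),
#'   `cost` (LOO misclassification fraction), `trace` (best cost after each
#'   start column), `method = "SPA"`, `start`, `size`.
#' @export
spa_select <- function(train, cfg = spa_config(), classes = NULL) {
  if (inherits(train, "spectral_dataset")) {
    validate_dataset(train, require_two_classes = TRUE)
    classes <- train$classes
    x <- train$intensities
  } else {
    x <- as.matrix(train)
  }
  stopifnot(inherits(cfg, "spa_config"))
  n <- nrow(x); p <- ncol(x)
  mmax <- min(cfg$max_vars, n - 3L, p)  # LOO folds need k <= (n-1) - 2
  if (mmax < 1L) stop("too few training rows for any subset size",
                      call. = FALSE)
  sizes <- cfg$candidate_sizes[cfg$candidate_sizes <= mmax]
  best <- list(cost = Inf, size = Inf, start = Inf, chain = NULL)
  trace <- numeric(p)
  any_ok <- FALSE
  for (start in seq_len(p)) {
    chain <- spa_chain(x, start, mmax, partial = TRUE)
    for (m in sizes[sizes <= length(chain)]) {
      cost <- tryCatch(loo_cost(x[, chain[seq_len(m)], drop = FALSE],
                                classes),
                       error = function(e) NA_real_)
      if (is.na(cost)) next
      any_ok <- TRUE
      if (cost < best$cost ||
          (cost == best$cost && (m < best$size ||
                                 (m == best$size && start < best$start)))) {
        best <- list(cost = cost, size = m, start = start,
                     chain = chain[seq_len(m)])
      }
    }
    trace[start] <- best$cost
  }
  if (!any_ok) {
    stop("every candidate subset failed LOO-LDA evaluation", call. = FALSE)
  }
  structure(list(selected_indices = sort(best$chain), cost = best$cost,
                 trace = trace, method = "SPA",
                 start = best$start, size = best$size),
            class = "selection_result")
}

#' GA-LDA variable selection
#'
#' Evolutionary search over subsets of at most `max_vars` distinct variable
#' indices. Fitness is `1 -` leave-one-out LDA misclassification on the
#' training partition; selection is tournament of size 2; crossover pools
#' the two parents' genes and deals them uniformly (then de-duplicates and
#' truncates to `max_vars`); mutation replaces each gene independently with
#' probability `mutation_rate` by a random unused index; elitism preserves
#' the best chromosomes, so the best-ever fitness is non-decreasing.
#' Deterministic given `cfg$seed`.
#'
#' @inheritParams spa_select
#' @param cfg a [ga_config()].
#' @return list of class `selection_result`: `selected_indices` (sorted),
#'   `cost`, `trace` (best-ever cost per generation), `method = "GA"`.
#' @export
ga_select <- function(train, cfg = ga_config(), classes = NULL) {
  if (inherits(train, "spectral_dataset")) {
    validate_dataset(train, require_two_classes = TRUE)
    classes <- train$classes
    x <- train$intensities
  } else {
    x <- as.matrix(train)
  }
  stopifnot(inherits(cfg, "ga_config"))
  n <- nrow(x); p <- ncol(x)
  kmax <- min(cfg$max_vars, n - 3L, p)
  if (kmax < 1L) stop("too few training rows for any subset size",
                      call. = FALSE)

  cache <- new.env(parent = emptyenv())
  fitness <- function(genes) {
    key <- paste(sort(genes), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- tryCatch(
      1 - loo_cost(x[, genes, drop = FALSE], classes),
      error = function(e) 0)
    cache[[key]] <- val
    val
  }

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  mutate <- function(genes) {
    hits <- which(stats::runif(length(genes)) < cfg$mutation_rate)
    for (g in hits) {
      unused <- setdiff(seq_len(p), genes)
      if (length(unused)) genes[g] <- unused[sample.int(length(unused), 1L)]
    }
    genes
  }
  crossover <- function(a, b) {
    pool <- c(a, b)
    pick1 <- stats::runif(length(pool)) < 0.5
    mk <- function(sel) {
      g <- unique(pool[sel])
      if (!length(g)) g <- pool[sample.int(length(pool), 1L)]
      if (length(g) > kmax) g <- g[seq_len(kmax)]
      g
    }
    list(mk(pick1), mk(!pick1))
  }
  tournament <- function(fits) {
    pair <- sample.int(length(fits), 2L)
    if (fits[pair[1]] >= fits[pair[2]]) pair[1] else pair[2]
  }

  pop <- lapply(seq_len(cfg$population), function(i) {
    sample.int(p, sample.int(kmax, 1L))
  })
  fits <- vapply(pop, fitness, numeric(1))
  best_i <- which.max(fits)
  best <- list(genes = pop[[best_i]], fit = fits[best_i])
  trace <- numeric(cfg$generations)
  for (gen in seq_len(cfg$generations)) {
    ord <- order(fits, decreasing = TRUE)
    newpop <- pop[ord[seq_len(min(cfg$elitism, cfg$population))]]
    while (length(newpop) < cfg$population) {
      pa <- pop[[tournament(fits)]]
      pb <- pop[[tournament(fits)]]
      if (stats::runif(1) < cfg$crossover_rate) {
        kids <- crossover(pa, pb)
      } else {
        kids <- list(pa, pb)
      }
      kids <- lapply(kids, mutate)
      newpop <- c(newpop, kids)
    }
    pop <- newpop[seq_len(cfg$population)]
    fits <- vapply(pop, fitness, numeric(1))
    gi <- which.max(fits)
    if (fits[gi] > best$fit) best <- list(genes = pop[[gi]], fit = fits[gi])
    trace[gen] <- 1 - best$fit
  }
  structure(list(selected_indices = sort(unique(best$genes)),
                 cost = 1 - best$fit, trace = trace, method = "GA"),
            class = "selection_result")
}

#' Per-variable Fisher weights and class attribution
#'
#' For each selected variable j, the Fisher weight
#' `(mean_Aj - mean_Bj)^2 / (var_Aj + var_Bj)` (unbiased variances) ranks
#' its discriminant contribution; the variable is attributed to the class
#' with the larger mean there. A zero pooled variance yields an infinite
#' weight, flagged rather than raised.
#'
#' @param train a two-class [spectral_dataset] (or matrix with `classes`).
#' @param indices column indices to report on.
#' @param classes per-row labels when `train` is a matrix.
#' @return data.frame with `index`, `axis_value` (NA for plain matrices),
#'   `weight`, `attributed_class`, `infinite` flag.
#' @export
fisher_weights <- function(train, indices, classes = NULL) {
  axis <- NULL
  if (inherits(train, "spectral_dataset")) {
    validate_dataset(train, require_two_classes = TRUE)
    classes <- train$classes
    axis <- train$axis
    x <- train$intensities
  } else {
    x <- as.matrix(train)
  }
  labs <- sort(unique(classes))
  stopifnot(length(labs) == 2L, min(table(classes)) >= 2L)
  xa <- x[classes == labs[1], indices, drop = FALSE]
  xb <- x[classes == labs[2], indices, drop = FALSE]
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- apply(xa, 2L, stats::var); vb <- apply(xb, 2L, stats::var)
  denom <- va + vb
  w <- ifelse(denom > 0, (ma - mb)^2 / denom,
              ifelse(ma == mb, 0, Inf))
  data.frame(
    index = as.integer(indices),
    axis_value = if (is.null(axis)) NA_real_ else axis[indices],
    weight = w,
    attributed_class = ifelse(ma >= mb, labs[1], labs[2]),
    infinite = is.infinite(w),
    stringsAsFactors = FALSE
  )
}
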