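#' K-medians clustering under the L1 metric
#'
#' Partitions rows of `x` into `k` clusters by alternating (i) assignment of
#' each point to the cluster whose coordinate-wise median is nearest in L1
#' (Manhattan) distance and (ii) recomputation of each cluster's
#' coordinate-wise median, until the summed L1 deviation changes by less than
#' `tol` or `max_iter` is reached. The best of `n_init` restarts (by final
#' objective) is returned. Initial medians are chosen by a k-means++-style
#' scheme adapted to L1 distances; a cluster that empties is re-seeded at the
#' point farthest (L1) from its current median.
#'
#' @param x Numeric matrix (or coercible), one row per observation.
#' @param k Number of clusters.
#' @param seed Optional integer seed for the restarts.
#' @param n_init Number of random restarts.
#' @param max_iter Maximum iterations per restart.
#' @param tol Convergence tolerance on the objective.
#' @return An object of class `kmedians`: `cluster` (assignments), `medians`
#'   (`k x d` matrix), `objective` (summed L1 deviation), `objective_trace`
#'   (per-iteration objective of the winning restart), `iter`, `converged`.
#' @export
kmedians <- function(x, k, seed = NULL, n_init = 10L, max_iter = 100L,
                     tol = 1e-6) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (any(!is.finite(x))) stop("invalid input: non-finite values in `x`")
  if (n < k) stop("insufficient data: fewer observations (", n,
                  ") than clusters (", k, ")")
  if (!is.null(seed)) set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_init)) {
    res <- .kmed_once(x, k, max_iter, tol)
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  structure(c(best, list(k = k, n = n)), class = "kmedians")
}

.l1_to_medians <- function(x, med) {
  # n x k matrix of L1 distances
  k <- nrow(med)
  sapply(seq_len(k), function(j) {
    rowSums(abs(x - rep(med[j, ], each = nrow(x))))
  })
}

.colmedians <- function(x) apply(x, 2, stats::median)

.kmed_pp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) {
    for (j in 2:k) {
      d <- .l1_to_medians(x, centers[seq_len(j - 1), , drop = FALSE])
      dmin <- if (j == 2) d[, 1] else apply(d, 1, min)
      if (all(dmin == 0)) {
        centers[j, ] <- x[sample.int(n, 1), ]
      } else {
        centers[j, ] <- x[sample.int(n, 1, prob = dmin), ]
      }
    }
  }
  centers
}

# L1 cost of a point set around its coordinate-wise median
.l1_cost <- function(xs) {
  if (nrow(xs) == 0) return(0)
  sum(abs(sweep(xs, 2, .colmedians(xs))))
}

# One Lloyd-style alternation from given starting medians.
.kmed_lloyd <- function(x, med, k, max_iter, tol) {
  n <- nrow(x)
  obj_prev <- Inf
  trace <- numeric(0)
  cl <- rep(1L, n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d <- .l1_to_medians(x, med)
    cl <- max.col(-d, ties.method = "first")
    # re-seed empty clusters at the point farthest from its own median
    empty <- setdiff(seq_len(k), unique(cl))
    for (e in empty) {
      cur <- d[cbind(seq_len(n), cl)]
      far <- which.max(cur)
      med[e, ] <- x[far, ]
      cl[far] <- e
      d <- .l1_to_medians(x, med)
      cl <- max.col(-d, ties.method = "first")
    }
    trace <- c(trace, sum(d[cbind(seq_len(n), cl)]))
    for (j in seq_len(k)) {
      med[j, ] <- .colmedians(x[cl == j, , drop = FALSE])
    }
    d2 <- .l1_to_medians(x, med)
    cl <- max.col(-d2, ties.method = "first")
    obj2 <- sum(d2[cbind(seq_len(n), cl)])
    if (abs(obj_prev - obj2) < tol) {
      trace <- c(trace, obj2)
      converged <- TRUE
      break
    }
    obj_prev <- obj2
  }
  d <- .l1_to_medians(x, med)
  cl <- max.col(-d, ties.method = "first")
  list(cluster = cl, medians = med,
       objective = sum(d[cbind(seq_len(n), cl)]),
       objective_trace = trace, iter = it, converged = converged)
}

.kmed_once <- function(x, k, max_iter, tol) {
  n <- nrow(x)
  res <- .kmed_lloyd(x, .kmed_pp_init(x, k), k, max_iter, tol)
  # single-point relocation refinement: alternation alone can stall in a
  # local optimum where moving one point (and re-computing both cluster
  # medians) still improves the objective; apply best-improvement moves,
  # re-running the alternation after each, until none improves
  for (pass in seq_len(30L)) {
    cl <- res$cluster
    cost <- vapply(seq_len(k), function(j)
      .l1_cost(x[cl == j, , drop = FALSE]), numeric(1))
    best_gain <- tol + 1e-12
    best_move <- NULL
    for (i in seq_len(n)) {
      from <- cl[i]
      if (sum(cl == from) == 1L) next
      donor_new <- .l1_cost(x[cl == from & seq_len(n) != i, , drop = FALSE])
      for (to in seq_len(k)) {
        if (to == from) next
        recv_new <- .l1_cost(x[cl == to | seq_len(n) == i, , drop = FALSE])
        gain <- (cost[from] + cost[to]) - (donor_new + recv_new)
        if (gain > best_gain) {
          best_gain <- gain
          best_move <- c(i, to)
        }
      }
    }
    if (is.null(best_move)) break
    cl[best_move[1]] <- best_move[2]
    med <- res$medians
    for (j in seq_len(k)) med[j, ] <- .colmedians(x[cl == j, , drop = FALSE])
    nxt <- .kmed_lloyd(x, med, k, max_iter, tol)
    if (nxt$objective >= res$objective - tol) break
    nxt$objective_trace <- c(res$objective_trace, nxt$objective_trace)
    res <- nxt
  }
  res
}

#' @export
print.kmedians <- function(x, ...) {
  cat("k-medians clustering: k =", x$k, ", n =", x$n,
      ", objective =", format(x$objective, digits = 6),
      if (x$converged) "(converged)" else "(max iterations reached)", "\n")
  cat("cluster sizes:", tabulate(x$cluster, x$k), "\n")
  invisible(x)
}
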