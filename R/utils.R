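# internal numerics shared across modules

clamp01 <- function(x, lo = 0, hi = 100) pmin(pmax(x, lo), hi)

# row-wise log-sum-exp, stable for large negative log-weights
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# all permutations of 1..n as a list (n <= 8 in practice)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (p in sub) {
      k <- k + 1L
      out[[k]] <- c(i, p + (p >= i))
    }
  }
  out
}

# minimise sum of cost[i, perm[i]] over permutations; returns the map from
# rows to columns.  Exact enumeration up to 7 classes, greedy beyond.
min_cost_assignment <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(n <= m)
  if (m <= 7L) {
    perms <- all_permutations(m)
    best <- NULL
    best_cost <- Inf
    for (p in perms) {
      idx <- p[seq_len(n)]
      total <- sum(cost[cbind(seq_len(n), idx)])
      if (total < best_cost) {
        best_cost <- total
        best <- idx
      }
    }
    return(best)
  }
  # greedy fallback for large problems
  assigned <- integer(n)
  free <- seq_len(m)
  ord <- order(apply(cost, 1L, min))
  for (i in ord) {
    j <- free[which.min(cost[i, free])]
    assigned[i] <- j
    free <- setdiff(free, j)
  }
  assigned
}

#' Align estimated class labels with reference labels
#'
#' Finds the permutation of estimated labels that maximises agreement with a
#' reference labelling (e.g. simulation ground truth), which is needed because
#' mixture-model class labels are arbitrary up to permutation.
#'
#' @param estimated Integer vector of estimated class labels (1..G).
#' @param reference Integer vector of reference labels, same length.
#' @param G Number of classes; defaults to the larger maximum of both vectors.
#'
#' @return A list with `mapping` (estimated label -> reference label),
#'   `relabelled` (estimated labels after applying the mapping) and
#'   `accuracy` (fraction agreeing with the reference).
#' @export
#' @examples
#' align_labels(c(2, 2, 1, 1), c(1, 1, 2, 2))$accuracy
align_labels <- function(estimated, reference, G = NULL) {
  stopifnot(length(estimated) == length(reference))
  G <- G %||% max(estimated, reference)
  tab <- matrix(0, G, G)
  for (k in seq_along(estimated)) {
    tab[estimated[k], reference[k]] <- tab[estimated[k], reference[k]] + 1
  }
  mapping <- min_cost_assignment(-tab)
  relabelled <- mapping[estimated]
  list(
    mapping = mapping,
    relabelled = relabelled,
    accuracy = mean(relabelled == reference)
  )
}

# derive a reproducible sub-seed (kept below 2^31) from a base seed
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) %% 1009L
}
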