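#' Cluster-analysis training/test split
#'
#' Divides a descriptor table so that the training set spans the whole
#' chemical space: k-means (k-means++ seeding, Euclidean metric) on z-scored
#' descriptor columns, then per-cluster test allocation proportional to
#' cluster size (largest-remainder rounding). Within each cluster the points
#' most extreme from the centroid are reserved for training and the test
#' members are drawn from the remaining points nearest the centroid, so test
#' compounds sit inside the region the training set covers.
#'
#' @param table A [descriptor_table()].
#' @param n_test Number of test compounds (0 <= n_test < n).
#' @param k_clusters Number of clusters; default `ceiling(n / 5)`.
#' @param seed Integer seed (clustering and allocation are deterministic
#'   given it).
#' @return An object of class `split_result`: list with `train_ids`,
#'   `test_ids` (disjoint, union = all ids) and `cluster_assignment` (named
#'   integer vector id -> cluster).
#' @export
cluster_split <- function(table, n_test, k_clusters = NULL, seed = 1) {
  stopifnot(inherits(table, "descriptor_table"))
  n <- nrow(table$values)
  if (n_test < 0 || n_test >= n) stop("n_test must satisfy 0 <= n_test < n")
  if (is.null(k_clusters)) k_clusters <- ceiling(n / 5)
  k_clusters <- max(1L, min(as.integer(k_clusters), n - n_test, n))
  ids <- table$compound_ids

  if (n_test == 0L) {
    assign <- stats::setNames(rep(1L, n), ids)
    return(structure(list(train_ids = ids, test_ids = character(0),
                          cluster_assignment = assign),
                     class = "split_result"))
  }

  Z <- scale(table$values)
  Z[, attr(Z, "scaled:scale") == 0] <- 0   # constant columns carry no distance
  Z <- Z[, , drop = FALSE]

  set.seed(as.integer(seed))
  km <- NULL
  for (attempt in seq_len(10L)) {
    centers <- kmeanspp_centers(Z, k_clusters)
    km <- tryCatch(stats::kmeans(Z, centers = centers, iter.max = 100),
                   error = function(e) NULL)
    if (!is.null(km) && all(tabulate(km$cluster, k_clusters) > 0)) break
    km <- NULL
  }
  if (is.null(km)) stop("k-means produced an empty cluster in 10 restarts")
  cl <- km$cluster

  sizes <- tabulate(cl, k_clusters)
  quota <- largest_remainder(sizes / sum(sizes) * n_test, n_test)
  # a cluster must keep >= 1 training member
  over <- which(quota >= sizes)
  while (length(over)) {
    excess <- sum(quota[over] - (sizes[over] - 1L))
    quota[over] <- sizes[over] - 1L
    room <- which(quota < sizes - 1L)
    for (j in room) {
      if (excess <= 0) break
      add <- min(excess, sizes[j] - 1L - quota[j])
      quota[j] <- quota[j] + add
      excess <- excess - add
    }
    if (excess > 0) stop("cannot place all test compounds while keeping every cluster in training")
    over <- which(quota >= sizes)
  }

  test_idx <- integer(0)
  for (j in seq_len(k_clusters)) {
    if (quota[j] == 0L) next
    members <- which(cl == j)
    dist_c <- sqrt(rowSums((Z[members, , drop = FALSE] -
                            matrix(km$centers[j, ], length(members),
                                   ncol(Z), byrow = TRUE))^2))
    ord <- members[order(dist_c, members)]   # nearest first, id-stable ties
    n_reserve <- min(length(members) - quota[j] - 1L,
                     max(1L, ceiling(length(members) * 0.2)))
    n_reserve <- max(0L, n_reserve)
    eligible <- if (n_reserve > 0) ord[seq_len(length(ord) - n_reserve)] else ord
    test_idx <- c(test_idx, eligible[seq_len(quota[j])])
  }
  test_ids <- ids[sort(test_idx)]
  structure(
    list(train_ids = setdiff(ids, test_ids), test_ids = test_ids,
         cluster_assignment = stats::setNames(cl, ids)),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("split: %d train / %d test across %d clusters\n",
              length(x$train_ids), length(x$test_ids),
              length(unique(x$cluster_assignment))))
  invisible(x)
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
kmeanspp_centers <- function(Z, k) {
  n <- nrow(Z)
  idx <- sample.int(n, 1L)
  for (j in seq_len(k - 1L)) {
    d2 <- apply(Z, 1, function(row)
      min(colSums((t(Z[idx, , drop = FALSE]) - row)^2)))
    d2[idx] <- 0
    if (sum(d2) == 0) {
      idx <- c(idx, sample(setdiff(seq_len(n), idx), 1L))
    } else {
      idx <- c(idx, sample.int(n, 1L, prob = d2))
    }
  }
  Z[idx, , drop = FALSE]
}

# round fractional quotas to integers summing to `total`
largest_remainder <- function(frac, total) {
  base <- floor(frac)
  rem <- frac - base
  short <- total - sum(base)
  if (short > 0) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1L
  }
  as.integer(base)
}

#' Apply a split to a descriptor table
#'
#' @param table A [descriptor_table()].
#' @param split A [cluster_split()] result.
#' @return List with `train` and `test` descriptor tables (`test` is `NULL`
#'   when the split has no test ids).
#' @export
apply_split <- function(table, split) {
  stopifnot(inherits(table, "descriptor_table"), inherits(split, "split_result"))
  take <- function(ids) {
    if (!length(ids)) return(NULL)
    i <- match(ids, table$compound_ids)
    descriptor_table(table$values[i, , drop = FALSE], table$activity[i],
                     compound_ids = ids)
  }
  list(train = take(split$train_ids), test = take(split$test_ids))
}
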