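#' Fuzzy C-means clustering of subjects
#'
#' Standard fuzzy C-means: alternating updates of cluster centroids
#' (membership-weighted means with exponent `m`) and soft memberships
#' (inverse-distance weights with exponent 2/(m - 1)) until the largest
#' membership change drops below `tol` or `max_iter` is reached. Each
#' subject receives a membership in \[0, 1\] per cluster, rows summing to 1;
#' hard labels are the argmax cluster, ties broken toward the lower cluster
#' index. Initial centroids are `centers` distinct subjects drawn with the
#' given seed, so runs are reproducible; the global RNG state is untouched.
#'
#' @param data Subjects x features: a numeric matrix with subject rownames,
#'   or a data frame whose first column is a subject identifier.
#' @param centers Number of clusters (>= 2; default 2).
#' @param m Fuzzifier exponent (> 1; default 2).
#' @param seed Integer seed for the centroid initialization.
#' @param tol Convergence tolerance on the membership change (default 1e-6).
#' @param max_iter Iteration cap (default 300).
#' @return A list of class `fcm_fit`: `subjects`, `membership` (subjects x
#'   clusters), `hard_labels` (integer), `centers` (cluster x feature
#'   matrix), `objective` (per-iteration trace, non-increasing),
#'   `iterations`, `converged`.
#' @export
fuzzy_cmeans <- function(data, centers = 2, m = 2, seed = 1,
                         tol = 1e-6, max_iter = 300) {
  x <- as_subject_matrix(data)
  n <- nrow(x)
  if (centers < 2) stop("at least 2 clusters are required", call. = FALSE)
  if (m <= 1) stop("the fuzzifier m must exceed 1", call. = FALSE)
  if (n < centers) stop("fewer subjects than clusters", call. = FALSE)
  if (nrow(unique(as.data.frame(x))) < centers) {
    stop("fewer distinct subject profiles than clusters", call. = FALSE)
  }
  init <- with_seed(seed, {
    # sample until the initial centroids are pairwise distinct
    repeat {
      idx <- sample.int(n, centers)
      if (nrow(unique(as.data.frame(x[idx, , drop = FALSE]))) == centers) break
    }
    idx
  })
  v <- x[init, , drop = FALSE]
  u <- membership_update(x, v, m)
  obj <- fcm_objective(x, v, u, m)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    um <- u^m
    v <- (t(um) %*% x) / colSums(um)
    u_new <- membership_update(x, v, m)
    obj <- c(obj, fcm_objective(x, v, u_new, m))
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) { converged <- TRUE; break }
  }
  hard <- apply(u, 1, which.max)  # which.max takes the lower index on ties
  rownames(u) <- rownames(x)
  colnames(u) <- paste0("cluster", seq_len(centers))
  structure(list(subjects = rownames(x),
                 membership = u,
                 hard_labels = as.integer(hard),
                 centers = v,
                 objective = obj,
                 iterations = iter,
                 converged = converged,
                 m = m, seed = seed),
            class = "fcm_fit")
}

membership_update <- function(x, v, m) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(v))) -
    2 * x %*% t(v) + outer(rep(1, nrow(x)), rowSums(v^2))
  d2 <- pmax(d2, 0)
  w <- d2^(-1 / (m - 1))
  zero <- d2 < .Machine$double.eps
  if (any(zero)) {
    # a point sitting on a centroid belongs to it fully (split among ties)
    hit <- rowSums(zero) > 0
    w[hit, ] <- 0
    w[zero] <- 1
  }
  w / rowSums(w)
}

fcm_objective <- function(x, v, u, m) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(v))) -
    2 * x %*% t(v) + outer(rep(1, nrow(x)), rowSums(v^2))
  sum(u^m * pmax(d2, 0))
}

as_subject_matrix <- function(data) {
  if (is.data.frame(data)) {
    if (!is.numeric(data[[1]])) {
      ids <- as.character(data[[1]])
      x <- as.matrix(data[, -1, drop = FALSE])
      rownames(x) <- ids
    } else {
      x <- as.matrix(data)
    }
  } else {
    x <- as.matrix(data)
  }
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("missing values in clustering input", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- paste0("subject", seq_len(nrow(x)))
  x
}

# Evaluate code under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Tag a two-cluster solution as low / high expressors
#'
#' For a two-cluster fit over selected marker genes, the cluster whose
#' subjects have the lower mean combined (summed) marker expression is
#' tagged `low`, the other `high`. Tags are a property of the subjects'
#' expression, so they are invariant to cluster index permutation.
#'
#' @param fit An `fcm_fit` with 2 clusters.
#' @param data The subjects x markers data the fit was computed on.
#' @return `fit` with an added `cluster_tags` element (character, one of
#'   `"low"`/`"high"` per cluster) and `subject_tags` (per subject).
#' @export
tag_clusters <- function(fit, data) {
  stopifnot(inherits(fit, "fcm_fit"))
  if (ncol(fit$membership) != 2L) stop("tagging requires exactly 2 clusters", call. = FALSE)
  x <- as_subject_matrix(data)
  combined <- rowSums(x)
  means <- tapply(combined, fit$hard_labels, mean)
  if (length(means) < 2L || means[["1"]] == means[["2"]]) {
    stop("cluster mean expression tie; tag clusters manually", call. = FALSE)
  }
  tags <- if (means[["1"]] < means[["2"]]) c("low", "high") else c("high", "low")
  fit$cluster_tags <- tags
  fit$subject_tags <- tags[fit$hard_labels]
  fit
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat(sprintf("# Fuzzy C-means fit: %d subjects, %d clusters, %d iteration(s)%s\n",
              length(x$subjects), ncol(x$membership), x$iterations,
              if (x$converged) "" else " (not converged)"))
  cat(sprintf("# objective: %.6g\n", utils::tail(x$objective, 1)))
  if (!is.null(x$cluster_tags)) {
    sizes <- table(factor(x$subject_tags, levels = c("low", "high")))
    cat(sprintf("# tags: low n=%d, high n=%d\n", sizes[["low"]], sizes[["high"]]))
  }
  invisible(x)
}
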