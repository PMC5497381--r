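# NeighborNet split networks: K2P+Gamma distances, circular ordering,
# non-negative least-squares split weights with a small-weight threshold,
# bootstrap supports, and SplitsTree-readable NEXUS output.

#' Kimura two-parameter distance with gamma rate correction
#'
#' Pairwise K2P distances at gamma shape `gamma_shape` (the no-gamma limit is
#' `gamma_shape = Inf`), with pairwise deletion of non-ACGT columns.
#' Saturated pairs (invalid log/power argument) are flagged and set to
#' `saturation_ceiling`.
#'
#' @param sequences named character vector of equal-length sequences.
#' @param gamma_shape gamma shape parameter alpha (default 0.29).
#' @param saturation_ceiling distance assigned to saturated pairs.
#' @return symmetric distance matrix with zero diagonal; attribute
#'   `saturated` lists flagged pairs.
#' @export
k2p_gamma_distance <- function(sequences, gamma_shape = 0.29,
                               saturation_ceiling = 10) {
  n <- length(sequences)
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("t%03d", seq_len(n))
  M <- seq_matrix(sequences)
  acgt <- matrix(M %in% c("A", "C", "G", "T"), nrow = n)
  purine <- matrix(M %in% c("A", "G"), nrow = n)
  D <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  saturated <- list()
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    ok <- acgt[i, ] & acgt[j, ]
    m <- sum(ok)
    if (m == 0L)
      stop("no comparable sites between ", names(sequences)[i], " and ",
           names(sequences)[j])
    diff <- M[i, ok] != M[j, ok]
    ts <- diff & (purine[i, ok] == purine[j, ok])   # transition
    P <- sum(ts) / m
    Q <- sum(diff & !ts) / m
    w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
    if (w1 <= 0 || w2 <= 0) {
      d <- saturation_ceiling
      saturated[[length(saturated) + 1L]] <-
        c(names(sequences)[i], names(sequences)[j])
    } else if (is.infinite(gamma_shape)) {
      d <- -0.5 * log(w1) - 0.25 * log(w2)
    } else {
      a <- gamma_shape
      d <- a / 2 * (w1^(-1 / a) - 1) + a / 4 * (w2^(-1 / a) - 1)
    }
    D[i, j] <- D[j, i] <- d
  }
  attr(D, "saturated") <- saturated
  D
}

#' Circular taxon ordering by NeighborNet agglomeration
#'
#' Produces the circular ordering underlying the split network via the
#' NeighborNet agglomeration (phangorn's implementation), canonicalised to a
#' fixed rotation and direction: the lexicographically smallest taxon first,
#' proceeding towards its lexicographically smaller neighbour.
#'
#' @param d symmetric distance matrix with taxon dimnames (>= 4 taxa).
#' @return character vector: the circular ordering of taxa.
#' @export
neighbornet_ordering <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 4L) stop("need at least 4 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  labels <- rownames(d) %||% sprintf("t%03d", seq_len(nrow(d)))
  dimnames(d) <- list(labels, labels)
  nn <- phangorn::neighborNet(d)
  cyc <- attr(nn$splits, "cycle")
  if (is.null(cyc)) {
    # star-like metric: no non-trivial splits, every ordering is valid;
    # the canonical choice is the sorted label order
    return(sort(labels))
  }
  ord <- attr(nn$splits, "labels")[cyc]
  canonical_cycle(ord)
}

# Canonical rotation/reflection of a circular ordering: smallest label first,
# direction towards the smaller of its two neighbours.
canonical_cycle <- function(ord) {
  n <- length(ord)
  i <- which.min(match(ord, sort(ord)))
  ord <- ord[((seq_len(n) + i - 2L) %% n) + 1L]
  if (ord[2] > ord[n]) ord <- c(ord[1], rev(ord[-1]))
  ord
}

split_key <- function(side, taxa) {
  ref <- min(taxa)
  s <- if (ref %in% side) sort(setdiff(taxa, side)) else sort(side)
  paste(s, collapse = "|")
}

#' Fit circular split weights by non-negative least squares
#'
#' Candidate splits are all contiguous arcs of the circular ordering; their
#' weights are fitted by non-negative least squares of split-path distances
#' to the observed distances (ordinary least squares with weights clamped at
#' zero, since negative split weights are meaningless), and splits below
#' `threshold` are dropped. Taxa at zero distance are merged first and
#' reported.
#'
#' @param d symmetric distance matrix.
#' @param ordering circular ordering from [neighbornet_ordering()].
#' @param threshold minimum retained split weight (default 1e-6).
#' @return object of class `mhc_splits_network`: `taxa`, `ordering`,
#'   `splits` (list of taxon sets), `weights`, `rss`, `merged`
#'   (duplicate-taxon groups represented by their first member).
#' @export
fit_split_weights <- function(d, ordering, threshold = 1e-6) {
  d <- as.matrix(d)
  taxa <- rownames(d)
  merged <- list()
  # merge zero-distance duplicates (singular design otherwise)
  keep <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d) - 1L)) {
    if (!keep[i]) next
    dup <- which(keep & seq_len(nrow(d)) > i & d[i, ] < 1e-12)
    if (length(dup)) {
      merged[[length(merged) + 1L]] <- c(taxa[i], taxa[dup])
      keep[dup] <- FALSE
    }
  }
  reps <- taxa[keep]
  ordering <- ordering[ordering %in% reps]
  dd <- d[reps, reps, drop = FALSE]
  n <- length(ordering)
  if (n < 4L) stop("fewer than 4 distinct taxa after merging duplicates")
  pairs <- utils::combn(n, 2L)
  pos <- match(reps, ordering)
  sides <- list()
  for (i in seq_len(n - 1L)) for (j in i:(n - 1L))
    sides[[length(sides) + 1L]] <- ordering[i:j]
  inside <- vapply(sides, function(s) ordering %in% s, logical(n))
  # design: split separates pair (p,q) iff exactly one endpoint inside
  npair <- ncol(pairs)
  A <- matrix(0, npair, length(sides))
  b <- numeric(npair)
  for (q in seq_len(npair)) {
    p1 <- pairs[1, q]; p2 <- pairs[2, q]
    A[q, ] <- inside[p1, ] != inside[p2, ]
    b[q] <- dd[ordering[p1], ordering[p2]]
  }
  fit <- pracma::lsqnonneg(A, b)
  w <- fit$x
  sel <- which(w >= threshold)
  out <- list(taxa = taxa, ordering = ordering,
              splits = sides[sel], weights = w[sel],
              rss = sum((A %*% w - b)^2), merged = merged)
  class(out) <- "mhc_splits_network"
  out
}

#' Build a NeighborNet split network from an alignment
#'
#' Convenience driver: K2P+Gamma distances, NeighborNet circular ordering,
#' non-negative least-squares split weights.
#'
#' @param sequences named character vector of aligned sequences.
#' @param gamma_shape gamma shape for the distance (default 0.29).
#' @param threshold minimum retained split weight.
#' @return `mhc_splits_network`.
#' @export
neighbor_net <- function(sequences, gamma_shape = 0.29, threshold = 1e-6) {
  d <- k2p_gamma_distance(sequences, gamma_shape)
  fit_split_weights(d, neighbornet_ordering(d), threshold)
}

#' Distances induced by a split network
#'
#' Sum of weights of the splits separating each taxon pair; on tree metrics
#' this reproduces the input distances.
#'
#' @param network `mhc_splits_network`.
#' @return symmetric matrix over `network$ordering`.
#' @export
induced_distances <- function(network) {
  taxa <- network$ordering
  n <- length(taxa)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (k in seq_along(network$splits)) {
    inside <- taxa %in% network$splits[[k]]
    sep <- outer(inside, inside, `!=`)
    D <- D + sep * network$weights[k]
  }
  D
}

#' Bootstrap supports for network splits
#'
#' Resamples alignment columns with replacement, rebuilds the full network
#' per replicate, and scores each split of the original network by the
#' percentage of replicates whose network contains the same bipartition
#' (bipartition equality of taxon sets, ignoring weights). The display
#' filter at `support_display_min` is presentation-only.
#'
#' @param sequences named character vector of aligned sequences.
#' @param n_replicates bootstrap replicates (default 1000).
#' @param support_display_min display threshold in percent (default 70).
#' @param seed integer seed.
#' @param gamma_shape,threshold passed to [neighbor_net()].
#' @return `mhc_splits_network` with `supports` (percent per split) and
#'   `display` (splits at or above the display threshold).
#' @export
bootstrap_supports <- function(sequences, n_replicates = 1000L,
                               support_display_min = 70, seed = 1L,
                               gamma_shape = 0.29, threshold = 1e-6) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  net <- neighbor_net(sequences, gamma_shape, threshold)
  taxa <- net$ordering
  keys <- vapply(net$splits, split_key, character(1), taxa = taxa)
  hits <- setNames(numeric(length(keys)), keys)
  L <- nchar(sequences[1])
  set.seed(seed)
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    M <- seq_matrix(sequences)[, cols, drop = FALSE]
    boot <- setNames(do.call(paste0, asplit(M, 2)), names(sequences))
    bnet <- tryCatch(neighbor_net(boot, gamma_shape, threshold),
                     error = function(e) NULL)
    if (is.null(bnet)) next
    bkeys <- vapply(bnet$splits, split_key, character(1), taxa = bnet$ordering)
    hits[keys %in% bkeys] <- hits[keys %in% bkeys] + 1
  }
  net$supports <- 100 * hits / n_replicates
  net$display <- net$supports[net$supports >= support_display_min]
  net
}

#' Write a split network as a SplitsTree-readable NEXUS file
#'
#' Emits Taxa, Distances (when given) and Splits blocks; split weights,
#' the circular cycle and bootstrap supports (as confidences) are included.
#'
#' @param network `mhc_splits_network`.
#' @param path output path.
#' @param d optional distance matrix for the Distances block.
#' @return `path`, invisibly.
#' @export
write_nexus_splits <- function(network, path, d = NULL) {
  taxa <- network$ordering
  n <- length(taxa)
  lines <- c("#NEXUS", "",
             "BEGIN Taxa;",
             sprintf("DIMENSIONS ntax=%d;", n),
             "TAXLABELS",
             sprintf("[%d] '%s'", seq_len(n), taxa),
             ";", "END;", "")
  if (!is.null(d)) {
    dd <- as.matrix(d)[taxa, taxa]
    lines <- c(lines, "BEGIN Distances;",
               sprintf("DIMENSIONS ntax=%d;", n),
               "FORMAT labels=left diagonal triangle=both;",
               "MATRIX",
               vapply(seq_len(n), function(i)
                 paste0("'", taxa[i], "' ",
                        paste(formatC(dd[i, ], format = "g", digits = 8),
                              collapse = " ")), character(1)),
               ";", "END;", "")
  }
  cyc <- match(taxa, taxa)  # ordering positions 1..n in taxa order
  conf <- network$supports %||% rep(100, length(network$splits))
  mat <- vapply(seq_along(network$splits), function(k) {
    idx <- sort(match(network$splits[[k]], taxa))
    sprintf("[%d, size=%d] \t%.8g \t%.4g \t %s,", k, length(idx),
            network$weights[k], conf[k], paste(idx, collapse = " "))
  }, character(1))
  lines <- c(lines, "BEGIN Splits;",
             sprintf("DIMENSIONS ntax=%d nsplits=%d;", n,
                     length(network$splits)),
             "FORMAT labels=no weights=yes confidences=yes;",
             sprintf("CYCLE %s;", paste(cyc, collapse = " ")),
             "MATRIX", mat, ";", "END;")
  writeLines(lines, path)
  invisible(path)
}
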