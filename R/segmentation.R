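#' @importFrom stats kmeans
NULL

# normalized cut of a bipartition (0/1 labels) of affinity matrix A
normalized_cut <- function(A, labels) {
  g0 <- labels == 0L; g1 <- !g0
  if (!any(g0) || !any(g1)) return(Inf)
  cut <- sum(A[g0, g1, drop = FALSE])
  if (cut == 0) return(0)
  d <- rowSums(A)
  vol0 <- sum(d[g0]); vol1 <- sum(d[g1])
  if (vol0 == 0 || vol1 == 0) return(Inf)
  cut * (1 / vol0 + 1 / vol1)
}

connected_components <- function(A) {
  m <- nrow(A)
  comp <- integer(m)
  cur <- 0L
  for (s in seq_len(m)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(A[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Bisect a similarity submatrix by normalized spectral clustering
#'
#' Negative similarities are clipped to zero to form a valid affinity
#' matrix. The two-way split is obtained from the second eigenvector of
#' the symmetric normalized Laplacian: the sign split is refined both by
#' 2-means on the two-dimensional spectral embedding (seeded, hence
#' deterministic) and by a sweep over eigenvector-ordered thresholds, and
#' the candidate with the smallest normalized cut is returned. A fully
#' disconnected affinity graph is split by connected components instead.
#' Group 0 is the group containing the lowest-index element.
#'
#' @param S m x m symmetric similarity matrix (m >= 2).
#' @param seed RNG seed for the 2-means refinement.
#' @return integer vector of 0/1 labels, both groups non-empty.
#' @export
spectral_bisect <- function(S, seed = 1L) {
  S <- as.matrix(S)
  m <- nrow(S)
  if (m < 2L) stop("cannot bisect fewer than 2 elements")
  if (m != ncol(S)) stop("similarity matrix must be square")
  A <- pmax((S + t(S)) / 2, 0)
  diag(A) <- 0
  comp <- connected_components(A)
  if (max(comp) > 1L) {
    labels <- as.integer(comp != comp[1L])
    if (!any(labels == 1L)) labels[m] <- 1L  # cannot happen with >1 comps
    return(labels)
  }
  d <- rowSums(A)
  Dn <- 1 / sqrt(d)
  Lsym <- diag(m) - Dn * t(Dn * t(A))  # I - D^-1/2 A D^-1/2
  ev <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  v1 <- ev$vectors[, m]        # smallest eigenvalue
  v2 <- ev$vectors[, m - 1L]   # Fiedler direction
  emb <- cbind(v1, v2)
  candidates <- list(as.integer(v2 < 0))
  # seeded 2-means refinement on the spectral embedding
  set.seed(seed)
  km <- tryCatch(stats::kmeans(emb, centers = 2L, nstart = 5L),
                 error = function(e) NULL)
  if (!is.null(km)) candidates <- c(candidates, list(km$cluster - 1L))
  # sweep cut along the ordering induced by the Fiedler vector
  ord <- order(v2)
  for (k in seq_len(m - 1L)) {
    lab <- integer(m)
    lab[ord[seq_len(k)]] <- 1L
    candidates <- c(candidates, list(lab))
  }
  scores <- vapply(candidates, function(lab) normalized_cut(A, lab), numeric(1L))
  best <- candidates[[which.min(scores)]]
  if (best[1L] == 1L) best <- 1L - best  # group of element 1 is labeled 0
  as.integer(best)
}

#' Five-level hierarchical spectral segmentation
#'
#' Recursively bisects the symmetrized co-heritability matrix: the whole
#' landmark set (level 0, segment 1) is split in two at level 1, each
#' segment is split again toward the next level, producing `2^l` segments
#' at level `l` and `2^(L+1) - 1` segments in total (63 for the default
#' five levels). Segment ids follow the binary-heap convention: the
#' children of segment `s` are `2 s` and `2 s + 1`. A segment too small
#' to split passes through unchanged (its landmarks go to child `2 s`)
#' with a warning and is flagged in the registry.
#'
#' @param m a symmetrized `coherit_matrix` (or plain symmetric matrix).
#' @param levels number of bisection levels (default 5).
#' @param seed RNG seed passed to [spectral_bisect()].
#' @return object of class `segmentation_hierarchy`: `labels`
#'   (K x (levels + 1) matrix of segment ids, one column per level),
#'   `registry` (tibble: `segment_id`, `level`, `parent`, `size`,
#'   `split_ok`), `levels`, `K`.
#' @export
build_hierarchy <- function(m, levels = 5L, seed = 1L) {
  S <- if (inherits(m, "coherit_matrix")) {
    if (!isTRUE(m$symmetrized)) stop("co-heritability matrix must be symmetrized first")
    m$values
  } else as.matrix(m)
  if (max(abs(S - t(S))) > 1e-8) stop("matrix must be symmetric")
  K <- nrow(S)
  labels <- matrix(NA_integer_, K, levels + 1L)
  labels[, 1L] <- 1L
  members <- list(`1` = seq_len(K))
  registry <- list(tibble::tibble(segment_id = 1L, level = 0L, parent = NA_integer_,
                                  size = K, split_ok = NA))
  warned <- FALSE
  for (l in seq_len(levels)) {
    new_members <- list()
    for (s in as.integer(names(members))) {
      if (s < 2^(l - 1L) || s >= 2^l) next  # only segments of level l-1
      idx <- members[[as.character(s)]]
      if (length(idx) >= 2L) {
        lab <- spectral_bisect(S[idx, idx, drop = FALSE],
                               seed = seed + s)
        g0 <- idx[lab == 0L]; g1 <- idx[lab == 1L]
        ok <- TRUE
      } else {
        if (!warned && length(idx) > 0L) {
          warning("segment of size < 2 reached before the final level; ",
                  "carried through unchanged")
          warned <- TRUE
        }
        g0 <- idx; g1 <- integer(0)
        ok <- FALSE
      }
      labels[g0, l + 1L] <- 2L * s
      labels[g1, l + 1L] <- 2L * s + 1L
      new_members[[as.character(2L * s)]] <- g0
      new_members[[as.character(2L * s + 1L)]] <- g1
      registry <- c(registry, list(tibble::tibble(
        segment_id = c(2L * s, 2L * s + 1L), level = l, parent = s,
        size = c(length(g0), length(g1)), split_ok = ok)))
    }
    members <- c(members, new_members)
  }
  structure(
    list(labels = labels, registry = dplyr::bind_rows(registry),
         members = members, levels = levels, K = K),
    class = "segmentation_hierarchy"
  )
}

#' @export
print.segmentation_hierarchy <- function(x, ...) {
  cat("<segmentation_hierarchy> ", x$levels, " levels, ",
      nrow(x$registry), " segments over K = ", x$K, " landmarks\n", sep = "")
  invisible(x)
}

#' Segment membership at one level
#' @param hierarchy a `segmentation_hierarchy`.
#' @param level level 0..levels.
#' @return integer vector of segment ids (length K).
#' @export
level_labels <- function(hierarchy, level) {
  stopifnot(level >= 0L, level <= hierarchy$levels)
  hierarchy$labels[, level + 1L]
}

#' @method tidy segmentation_hierarchy
#' @export
tidy.segmentation_hierarchy <- function(x, ...) x$registry

#' Normalized mutual information between two labelings
#'
#' Mutual information normalized by the arithmetic mean of the two label
#' entropies. Identical labelings score 1 — including the degenerate
#' single-cluster case, where both entropies vanish — and independent
#' labelings score 0. Invariant to label permutation and symmetric in
#' its arguments.
#'
#' @param a,b label vectors of equal length.
#' @return scalar in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  n <- length(a)
  tab <- table(a, b)
  p <- tab / n
  pa <- rowSums(p); pb <- colSums(p)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha + hb == 0) return(1)  # both single-cluster: identical by definition
  outer_p <- outer(pa, pb)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer_p[nz]))
  max(0, min(1, mi / ((ha + hb) / 2)))
}
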