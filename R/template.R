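#' Construct a landmark template mesh
#'
#' A template mesh fixes the landmark topology shared by every subject: the
#' number of landmarks `K`, a triangulation over them, and the bilateral
#' correspondence used for symmetry analysis. Every landmark index belongs
#' either to exactly one left--right pair or to the midline (the sagittal
#' plane, `x = 0` after alignment). All indices are 0-based, matching the
#' on-disk formats.
#'
#' @param vertices K x 3 numeric matrix of template landmark coordinates.
#' @param faces integer matrix with 3 columns of 0-based vertex indices
#'   (may have zero rows for a point-cloud template).
#' @param bilateral_pairs two-column integer matrix of 0-based
#'   `(left, right)` landmark index pairs.
#' @param midline integer vector of 0-based landmark indices on the
#'   sagittal plane.
#'
#' @return An object of class `template_mesh` with fields `vertices`,
#'   `faces`, `bilateral_pairs`, `midline` and `K`.
#' @export
template_mesh <- function(vertices, faces, bilateral_pairs, midline) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L) stop("template vertices must be K x 3")
  K <- nrow(vertices)
  faces <- matrix(as.integer(faces), ncol = 3L)
  bilateral_pairs <- matrix(as.integer(bilateral_pairs), ncol = 2L)
  midline <- as.integer(midline)
  obj <- structure(
    list(vertices = vertices, faces = faces,
         bilateral_pairs = bilateral_pairs, midline = midline, K = K),
    class = "template_mesh"
  )
  validate_template(obj)
  obj
}

#' @export
print.template_mesh <- function(x, ...) {
  cat("<template_mesh> ", x$K, " landmarks, ", nrow(x$faces), " faces, ",
      nrow(x$bilateral_pairs), " bilateral pairs, ",
      length(x$midline), " midline landmarks\n", sep = "")
  invisible(x)
}

validate_template <- function(template) {
  K <- template$K
  bp <- template$bilateral_pairs
  ml <- template$midline
  if (any(!is.finite(template$vertices))) stop("template vertices must be finite")
  if (nrow(template$faces) > 0L) {
    if (min(template$faces) < 0L || max(template$faces) >= K)
      stop("face indices must lie in [0, K)")
  }
  idx <- c(bp[, 1L], bp[, 2L], ml)
  if (length(idx) != K || anyDuplicated(idx) || !setequal(idx, 0:(K - 1L)))
    stop("every landmark must appear exactly once across bilateral pairs and midline")
  # pair map must be an involution with no self-pairs
  if (nrow(bp) > 0L && any(bp[, 1L] == bp[, 2L]))
    stop("bilateral pair cannot map a landmark to itself")
  invisible(template)
}

#' Full landmark index permutation induced by the bilateral pair map
#'
#' Returns a 1-based permutation `perm` such that `perm[i]` is the mirror
#' partner of landmark `i` (midline landmarks map to themselves).
#'
#' @param template a [template_mesh()].
#' @return integer vector of length `K` (1-based).
#' @keywords internal
pair_permutation <- function(template) {
  perm <- seq_len(template$K)
  bp <- template$bilateral_pairs + 1L
  perm[bp[, 1L]] <- bp[, 2L]
  perm[bp[, 2L]] <- bp[, 1L]
  perm
}

#' Per-vertex unit normals of a template mesh
#'
#' Face normals are area-weighted and accumulated on vertices, then
#' normalized. Vertices touching no face get the zero vector.
#'
#' @param template a [template_mesh()].
#' @return K x 3 matrix of unit normals.
#' @export
vertex_normals <- function(template) {
  V <- template$vertices
  Fc <- template$faces + 1L
  N <- matrix(0, nrow(V), 3L)
  if (nrow(Fc) > 0L) {
    a <- V[Fc[, 1L], , drop = FALSE]
    e1 <- V[Fc[, 2L], , drop = FALSE] - a
    e2 <- V[Fc[, 3L], , drop = FALSE] - a
    fn <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
                e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
                e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
    for (j in 1:3) {
      for (d in 1:3) {
        acc <- rowsum(fn[, d], Fc[, j])
        N[as.integer(rownames(acc)), d] <- N[as.integer(rownames(acc)), d] + acc[, 1L]
      }
    }
  }
  len <- sqrt(rowSums(N^2))
  ok <- len > 0
  N[ok, ] <- N[ok, , drop = FALSE] / len[ok]
  N
}

#' Synthetic bilaterally symmetric paraboloid template
#'
#' Builds a "face-like" test surface: a paraboloid `z = -(x^2 + y^2) / c`
#' sampled on a regular grid mirrored about `x = 0`. Columns are placed
#' symmetrically around the sagittal plane; with an odd number of columns
#' the central column is the midline, otherwise there is no midline
#' landmark. Bilateral pairs connect mirrored columns within each row.
#'
#' @param grid_shape integer `(rows, cols)`, both at least 2.
#' @param curvature paraboloid flattening constant `c` (default 4).
#' @return a [template_mesh()] with `K = rows * cols` landmarks.
#' @export
make_template <- function(grid_shape, curvature = 4) {
  rows <- as.integer(grid_shape[1L]); cols <- as.integer(grid_shape[2L])
  if (rows < 2L || cols < 2L) stop("grid_shape entries must be >= 2")
  # x symmetric about 0; odd cols puts a column exactly at x = 0
  xs <- seq(-1, 1, length.out = cols)
  xs <- (xs - rev(xs)) / 2  # force exact antisymmetry in floating point
  ys <- seq(-1, 1, length.out = rows)
  g <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  x <- xs[g$col]; y <- ys[g$row]
  z <- -(x^2 + y^2) / curvature
  vertices <- cbind(x, y, z)
  # index helper: landmark of (row r, col c), 0-based
  idx <- function(r, c) (r - 1L) * cols + (c - 1L)
  # triangulate grid cells
  faces <- NULL
  if (rows > 1L && cols > 1L) {
    r <- rep(seq_len(rows - 1L), each = cols - 1L)
    c <- rep(seq_len(cols - 1L), times = rows - 1L)
    v00 <- idx(r, c); v01 <- idx(r, c + 1L)
    v10 <- idx(r + 1L, c); v11 <- idx(r + 1L, c + 1L)
    faces <- rbind(cbind(v00, v01, v11), cbind(v00, v11, v10))
  }
  half <- cols %/% 2L
  midline <- integer(0)
  if (cols %% 2L == 1L) midline <- idx(seq_len(rows), half + 1L)
  left <- right <- integer(0)
  for (c in seq_len(half)) {
    left <- c(left, idx(seq_len(rows), c))
    right <- c(right, idx(seq_len(rows), cols + 1L - c))
  }
  template_mesh(vertices, faces, cbind(left, right), midline)
}
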