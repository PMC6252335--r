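#' Paired father-offspring cohort of landmark configurations
#'
#' Bundles the two cohorts of corresponded landmark configurations with the
#' family links and the covariates used for confounder adjustment. Each
#' father appears at most once (one child per family) and every paired
#' subject must have complete age / sex / BMI covariates.
#'
#' @param fathers n x K x 3 array of father configurations; first dimnames
#'   are subject ids.
#' @param offspring n x K x 3 array of offspring configurations, row i
#'   paired with father row i; first dimnames are subject ids.
#' @param covariates data frame with columns `subject_id`, `age` (years),
#'   `sex` ("M"/"F"), `bmi` (kg/m^2), one row per subject in either cohort.
#' @param template a [template_mesh()].
#'
#' @return An object of class `paired_cohort` with fields `fathers`,
#'   `offspring`, `covariates` (a tibble), `template` and `n_pairs`.
#' @export
paired_cohort <- function(fathers, offspring, covariates, template) {
  stopifnot(length(dim(fathers)) == 3L, length(dim(offspring)) == 3L)
  if (dim(fathers)[1L] != dim(offspring)[1L])
    stop("fathers and offspring must have the same number of rows (pairs)")
  K <- template$K
  if (dim(fathers)[2L] != K || dim(offspring)[2L] != K)
    stop("configuration landmark count does not match template (dimension mismatch)")
  if (dim(fathers)[3L] != 3L || dim(offspring)[3L] != 3L)
    stop("configurations must be K x 3")
  fid <- dimnames(fathers)[[1L]]; oid <- dimnames(offspring)[[1L]]
  if (is.null(fid) || is.null(oid)) stop("subject ids required as dimnames")
  if (anyDuplicated(fid) || anyDuplicated(oid) || any(fid %in% oid))
    stop("duplicate subject_id")
  if (!all(is.finite(fathers)) || !all(is.finite(offspring)))
    stop("all coordinates must be finite")
  covariates <- tibble::as_tibble(covariates)
  need <- c("subject_id", "age", "sex", "bmi")
  if (!all(need %in% names(covariates))) stop("covariates need subject_id, age, sex, bmi")
  ids <- c(fid, oid)
  cv <- covariates[match(ids, covariates$subject_id), ]
  if (any(is.na(cv$subject_id)) || any(is.na(cv$age)) || any(is.na(cv$bmi)) ||
      any(is.na(cv$sex)))
    stop("every paired subject must have complete covariates")
  if (!all(cv$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  structure(
    list(fathers = fathers, offspring = offspring,
         covariates = tibble::as_tibble(cv), template = template,
         n_pairs = dim(fathers)[1L]),
    class = "paired_cohort"
  )
}

#' @export
print.paired_cohort <- function(x, ...) {
  sex <- offspring_sex(x)
  cat("<paired_cohort> ", x$n_pairs, " father-offspring pairs, K = ",
      x$template$K, " landmarks (", sum(sex == "M"), " sons, ",
      sum(sex == "F"), " daughters)\n", sep = "")
  invisible(x)
}

#' Offspring sex labels of a cohort, in pair order
#' @param cohort a [paired_cohort()].
#' @return character vector of "M"/"F".
#' @export
offspring_sex <- function(cohort) {
  ids <- dimnames(cohort$offspring)[[1L]]
  cohort$covariates$sex[match(ids, cohort$covariates$subject_id)]
}

#' Per-landmark scalar field (e.g. a heritability map)
#'
#' @param values numeric vector of length `K`.
#' @param template a [template_mesh()].
#' @param name label used in file headers and plots.
#' @return object of class `scalar_field`.
#' @export
scalar_field <- function(values, template, name = "value") {
  values <- as.numeric(values)
  if (length(values) != template$K) stop("scalar field length must equal K")
  if (any(!is.finite(values))) stop("scalar field values must be finite")
  structure(list(values = values, template = template, name = name),
            class = "scalar_field")
}

# ---- delimited readers/writers -------------------------------------------

write_xyz <- function(coords, path) {
  utils::write.table(format(coords, digits = 17, scientific = TRUE, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE, quote = FALSE)
}

read_xyz <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' Write a cohort to a directory of plain-text files
#'
#' Layout: `configs/<subject_id>.xyz` (K rows of `x y z`), `pairing.csv`
#' (`offspring_id,father_id`) and `covariates.csv`
#' (`subject_id,age,sex,bmi`). Coordinates round-trip bit-exactly.
#'
#' @param cohort a [paired_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "configs"), recursive = TRUE, showWarnings = FALSE)
  all_ids <- c(dimnames(cohort$fathers)[[1L]], dimnames(cohort$offspring)[[1L]])
  coords <- function(id) {
    n <- dim(cohort$fathers)[1L]
    i <- match(id, dimnames(cohort$fathers)[[1L]])
    if (!is.na(i)) cohort$fathers[i, , ] else
      cohort$offspring[match(id, dimnames(cohort$offspring)[[1L]]), , ]
  }
  for (id in all_ids) write_xyz(coords(id), file.path(dir, "configs", paste0(id, ".xyz")))
  pairing <- data.frame(offspring_id = dimnames(cohort$offspring)[[1L]],
                        father_id = dimnames(cohort$fathers)[[1L]])
  utils::write.csv(pairing, file.path(dir, "pairing.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(cohort$covariates), file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from a directory of plain-text files
#'
#' Reads the layout written by [write_cohort()]. Pairs in which either
#' subject lacks a configuration file or any covariate are excluded, with
#' the exclusion count reported via `message()`; structural problems
#' (dimension mismatch with the template, duplicate ids, an empty pairing
#' table) are hard errors.
#'
#' @param dir directory containing `configs/`, `pairing.csv`,
#'   `covariates.csv`.
#' @param template a [template_mesh()]; configurations must match its `K`.
#' @return a validated [paired_cohort()].
#' @export
read_cohort <- function(dir, template) {
  pairing <- utils::read.csv(file.path(dir, "pairing.csv"),
                             colClasses = "character")
  if (nrow(pairing) == 0L) stop("no pairs in pairing table")
  if (anyDuplicated(pairing$offspring_id) || anyDuplicated(pairing$father_id))
    stop("pairing must be one-to-one (one child per family)")
  cov <- utils::read.csv(file.path(dir, "covariates.csv"))
  cov$subject_id <- as.character(cov$subject_id)

  has_config <- function(id) file.exists(file.path(dir, "configs", paste0(id, ".xyz")))
  complete <- function(id) {
    i <- match(id, cov$subject_id)
    !is.na(i) && !anyNA(cov[i, c("age", "sex", "bmi")])
  }
  ok <- vapply(seq_len(nrow(pairing)), function(i) {
    o <- pairing$offspring_id[i]; f <- pairing$father_id[i]
    has_config(o) && has_config(f) && complete(o) && complete(f)
  }, logical(1L))
  if (sum(!ok) > 0L)
    message(sum(!ok), " pair(s) excluded for missing configurations or covariates")
  pairing <- pairing[ok, , drop = FALSE]
  if (nrow(pairing) == 0L) stop("no pairs remain after exclusions")

  load_set <- function(ids) {
    arr <- array(NA_real_, c(length(ids), template$K, 3L),
                 dimnames = list(ids, NULL, c("x", "y", "z")))
    for (i in seq_along(ids)) {
      m <- read_xyz(file.path(dir, "configs", paste0(ids[i], ".xyz")))
      if (nrow(m) != template$K || ncol(m) != 3L)
        stop("configuration '", ids[i], "' does not match template dimensions")
      arr[i, , ] <- m
    }
    arr
  }
  paired_cohort(load_set(pairing$father_id), load_set(pairing$offspring_id),
                cov, template)
}

# ---- mesh formats ---------------------------------------------------------

#' Write an ASCII PLY mesh, optionally with a per-vertex scalar property
#'
#' @param vertices K x 3 matrix.
#' @param faces 0-based triangle index matrix (possibly 0 rows).
#' @param path output file.
#' @param scalar optional K-vector written as the per-vertex property
#'   `quality`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(vertices, faces, path, scalar = NULL) {
  K <- nrow(vertices)
  con <- file(path, "w")
  on.exit(close(con))
  props <- c("property double x", "property double y", "property double z")
  if (!is.null(scalar)) {
    stopifnot(length(scalar) == K)
    props <- c(props, "property double quality")
  }
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", K), props,
               paste("element face", nrow(faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  vm <- if (is.null(scalar)) vertices else cbind(vertices, scalar)
  writeLines(apply(format(vm, digits = 17, scientific = TRUE, trim = TRUE),
                   1L, paste, collapse = " "), con)
  if (nrow(faces) > 0L)
    writeLines(paste(3L, faces[, 1L], faces[, 2L], faces[, 3L]), con)
  invisible(path)
}

#' Read an ASCII PLY mesh
#'
#' @param path PLY file written by [write_ply()] or any ASCII PLY whose
#'   vertex element starts with x, y, z properties.
#' @return list with `vertices` (K x 3), `faces` (0-based), and `scalar`
#'   (the fourth vertex property, or NULL).
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  header <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", header, value = TRUE)))
  if (length(nf) == 0L) nf <- 0L
  vprops <- grep("^property (double|float)", header, value = TRUE)
  body <- lines[(end + 1L):length(lines)]
  vmat <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                                function(x) as.numeric(x)))
  vertices <- vmat[, 1:3, drop = FALSE]
  scalar <- if (length(vprops) >= 4L) vmat[, 4L] else NULL
  faces <- matrix(integer(0), 0L, 3L)
  if (nf > 0L) {
    fmat <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                                  function(x) as.integer(x)))
    faces <- fmat[, 2:4, drop = FALSE]
  }
  list(vertices = vertices, faces = faces, scalar = scalar)
}

read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  vertices <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                                    function(x) as.numeric(x[2:4])))
  faces <- matrix(integer(0), 0L, 3L)
  if (length(fl) > 0L) {
    faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
      as.integer(sub("/.*", "", x[2:4])) - 1L  # OBJ is 1-based
    }))
  }
  list(vertices = vertices, faces = faces)
}

#' Write a template mesh to a directory
#'
#' Emits `template.ply`, `bilateral_pairs.csv` (`left,right`, 0-based) and
#' `midline.csv` (`index`, 0-based).
#'
#' @param template a [template_mesh()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_template <- function(template, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ply(template$vertices, template$faces, file.path(dir, "template.ply"))
  utils::write.csv(data.frame(left = template$bilateral_pairs[, 1L],
                              right = template$bilateral_pairs[, 2L]),
                   file.path(dir, "bilateral_pairs.csv"), row.names = FALSE)
  utils::write.csv(data.frame(index = template$midline),
                   file.path(dir, "midline.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a template mesh from a directory
#'
#' Expects a `template.ply` or `template.obj` mesh plus
#' `bilateral_pairs.csv` and `midline.csv` with 0-based indices.
#'
#' @param dir directory written by [write_template()] (or hand-assembled).
#' @return a [template_mesh()].
#' @export
read_template <- function(dir) {
  ply <- file.path(dir, "template.ply"); obj <- file.path(dir, "template.obj")
  mesh <- if (file.exists(ply)) read_ply(ply) else if (file.exists(obj))
    read_obj(obj) else stop("no template.ply or template.obj in ", dir)
  bp <- utils::read.csv(file.path(dir, "bilateral_pairs.csv"))
  ml <- utils::read.csv(file.path(dir, "midline.csv"))
  template_mesh(mesh$vertices, mesh$faces,
                cbind(bp$left, bp$right), ml$index)
}

#' Write a per-landmark scalar field as CSV and colored PLY
#'
#' @param field a [scalar_field()].
#' @param path base path; writes `<path>.csv` (columns `index,value`,
#'   0-based) and `<path>.ply` (scalar as per-vertex `quality`).
#' @return character vector of the two file paths, invisibly.
#' @export
write_scalar_field <- function(field, path) {
  template <- field$template
  csv <- paste0(path, ".csv"); ply <- paste0(path, ".ply")
  df <- data.frame(index = 0:(template$K - 1L), value = field$values)
  names(df)[2L] <- field$name
  utils::write.csv(df, csv, row.names = FALSE)
  write_ply(template$vertices, template$faces, ply, scalar = field$values)
  invisible(c(csv, ply))
}

#' Read back a scalar field CSV written by [write_scalar_field()]
#' @param path the `.csv` path.
#' @param template a [template_mesh()].
#' @return a [scalar_field()].
#' @export
read_scalar_field <- function(path, template) {
  df <- utils::read.csv(path)
  scalar_field(df[[2L]], template, name = names(df)[2L])
}
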