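# Single-shell acquisition schemes and FSL-style bval/bvec tables.
# The emulated acquisition is b = 1000 s/mm^2 in n non-collinear directions
# plus >= 1 (default 4) b = 0 volumes; desk-scale default is 32 directions,
# scaled down from the acquired 64.

#' Construct a single-shell acquisition scheme
#'
#' Directions are spread quasi-uniformly over the half-sphere with a golden
#' angle (Fibonacci) spiral, which guarantees non-collinearity.
#'
#' @param n_dirs number of diffusion-weighted directions (default 32; the
#'   acquisition this emulates used 64).
#' @param n_b0 number of b = 0 volumes (default 4).
#' @param bval b-value in s/mm^2 for the weighted volumes (default 1000).
#' @return an \code{acq_scheme}: list with \code{bvals} (length n_b0 + n_dirs)
#'   and \code{bvecs} (3 x n matrix; zero columns for b = 0 volumes).
#' @export
make_scheme <- function(n_dirs = 32L, n_b0 = 4L, bval = 1000) {
  stopifnot(n_dirs >= 6L, n_b0 >= 1L, bval > 0)
  i <- seq_len(n_dirs) - 0.5
  z <- i / n_dirs                       # half-sphere: z in (0, 1)
  phi <- pi * (1 + sqrt(5)) * i
  st <- sqrt(1 - z^2)
  dirs <- rbind(st * cos(phi), st * sin(phi), z)
  bvecs <- cbind(matrix(0, 3, n_b0), dirs)
  bvals <- c(rep(0, n_b0), rep(bval, n_dirs))
  acq_scheme(bvals, bvecs)
}

#' Create/validate an acquisition scheme from raw tables
#'
#' @param bvals numeric vector of b-values (s/mm^2).
#' @param bvecs 3 x n matrix of gradient directions; non-zero-b columns must
#'   be unit vectors (renormalized with a warning if off by more than 1e-3).
#' @export
acq_scheme <- function(bvals, bvecs) {
  bvecs <- unname(as.matrix(bvecs))
  if (nrow(bvecs) != 3L) stop("bvecs must be a 3 x n matrix", call. = FALSE)
  if (length(bvals) != ncol(bvecs)) {
    stop("scheme length mismatch: ", length(bvals), " b-values vs ",
         ncol(bvecs), " directions", call. = FALSE)
  }
  nz <- bvals > 0
  if (any(nz)) {
    nrm <- sqrt(colSums(bvecs[, nz, drop = FALSE]^2))
    if (any(nrm == 0)) stop("zero direction for non-zero b-value", call. = FALSE)
    if (any(abs(nrm - 1) > 1e-3)) {
      warning("renormalizing gradient directions (max |norm - 1| = ",
              format(max(abs(nrm - 1))), ")")
    }
    bvecs[, nz] <- sweep(bvecs[, nz, drop = FALSE], 2, nrm, "/")
  }
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs),
            class = "acq_scheme")
}

#' @export
print.acq_scheme <- function(x, ...) {
  cat("<acq_scheme> ", length(x$bvals), " volumes (",
      sum(x$bvals == 0), " b=0, b_max = ", max(x$bvals), " s/mm^2)\n", sep = "")
  invisible(x)
}

n_volumes <- function(scheme) length(scheme$bvals)

#' Read an FSL-style bval/bvec pair
#'
#' \code{bval}: one whitespace-separated row of b-values. \code{bvec}: three
#' rows of x/y/z direction components.
#'
#' @param bval_path,bvec_path file paths.
#' @return an \code{\link{acq_scheme}}.
#' @export
read_bvalbvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  rows <- readLines(bvec_path)
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != 3L) {
    stop("bvec file must have exactly 3 rows, found ", length(rows),
         call. = FALSE)
  }
  comp <- lapply(rows, function(r) scan(text = r, what = numeric(), quiet = TRUE))
  lens <- vapply(comp, length, 1L)
  if (length(unique(lens)) != 1L) {
    stop("bvec rows have differing lengths: ", paste(lens, collapse = ", "),
         call. = FALSE)
  }
  if (lens[1] != length(bvals)) {
    stop("bval/bvec length mismatch: ", length(bvals), " b-values vs ",
         lens[1], " direction columns", call. = FALSE)
  }
  acq_scheme(bvals, do.call(rbind, comp))
}

#' Write an FSL-style bval/bvec pair
#' @param scheme an \code{\link{acq_scheme}}.
#' @param bval_path,bvec_path output paths.
#' @export
write_bvalbvec <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(scheme$bvecs, 1, function(r) {
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")
  }), bvec_path)
  invisible(NULL)
}
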