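#' Close a composition to unit sum
#'
#' Divides each part by the total so the vector lies on the unit simplex.
#' Idempotent; relative information is unchanged.
#'
#' @param parts Numeric vector (or matrix with compositions in rows) of
#'   non-negative parts with positive total.
#' @return Vector (or matrix) of the same shape summing to 1 per composition.
#' @examples
#' close_composition(c(83.4, 1.1, 2.7, 2.5, 2.0))
#' @export
close_composition <- function(parts) {
  if (is.matrix(parts)) {
    if (anyNA(parts) || any(parts < 0)) stop("parts must be non-negative")
    tot <- rowSums(parts)
    if (any(tot <= 0)) stop("each composition must have a positive total")
    return(parts / tot)
  }
  if (anyNA(parts) || any(parts < 0)) stop("parts must be non-negative")
  tot <- sum(parts)
  if (tot <= 0) stop("cannot close an all-zero composition")
  parts / tot
}

#' Multiplicative zero replacement
#'
#' Replaces zero parts of a closed composition by a small fraction `delta`
#' and rescales the non-zero parts multiplicatively so closure is preserved.
#' Zeros in counted differentials are sampling zeros: a class can be missed
#' whenever its true frequency is below the minimum detectable frequency
#' implied by the counting floor, so the default `delta` sits at 65% of
#' 1/150 (i.e. below one cell in 150).
#'
#' @param parts Closed composition (vector, or matrix with rows as
#'   compositions).
#' @param delta Replacement fraction, 0 < delta < smallest non-zero part.
#' @return Strictly positive closed composition of the same shape.
#' @examples
#' replace_zeros(c(1, 0, 0, 0, 0), delta = 0.001)
#' @export
replace_zeros <- function(parts, delta = 0.65 / 150) {
  if (is.matrix(parts)) {
    return(t(apply(parts, 1L, replace_zeros, delta = delta)))
  }
  if (abs(sum(parts) - 1) > 1e-9)
    stop("'parts' must be a closed composition (sum 1)")
  z <- parts == 0
  if (!any(z)) return(parts)
  if (length(delta) != 1L || is.na(delta) || delta <= 0)
    stop("'delta' must be a single positive fraction")
  if (delta >= min(parts[!z]))
    stop("'delta' (", delta, ") must be below the smallest non-zero part (",
         signif(min(parts[!z]), 6), ")")
  out <- parts
  out[z] <- delta
  out[!z] <- parts[!z] * (1 - sum(z) * delta)
  out
}

#' Orthonormal ilr contrast basis
#'
#' Builds the (D-1) x D contrast matrix of the canonical sequential-binary-
#' partition isometric log-ratio basis in the fixed class order: coordinate k
#' balances the geometric mean of the first k parts against part k+1. Rows
#' are unit-norm, mutually orthogonal and sum to zero, so the matrix is
#' orthonormal in the centered log-ratio geometry. For D = 2 the single
#' coordinate is ln(x1/x2)/sqrt(2).
#'
#' @param D Number of parts (default 5, the leukocyte differential).
#' @param part_names Optional column names (defaults to [leukocyte_classes]
#'   when D = 5).
#' @return A (D-1) x D numeric contrast matrix.
#' @export
ilr_basis <- function(D = 5, part_names = NULL) {
  if (D < 2) stop("'D' must be at least 2")
  V <- matrix(0, D - 1L, D)
  for (k in seq_len(D - 1L)) {
    V[k, seq_len(k)] <- sqrt(1 / (k * (k + 1)))
    V[k, k + 1L] <- -sqrt(k / (k + 1))
  }
  if (is.null(part_names) && D == 5L) part_names <- leukocyte_classes
  dimnames(V) <- list(paste0("ilr", seq_len(D - 1L)), part_names)
  V
}

#' Isometric log-ratio transform
#'
#' Maps a strictly positive closed D-part composition to D-1 Euclidean
#' coordinates, `coords = basis %*% log(parts)`. The map is an isometry
#' between the Aitchison geometry on the simplex and ordinary Euclidean
#' geometry, which is what licenses using the coordinates as responses in a
#' linear model.
#'
#' @param parts Strictly positive closed composition (vector, or matrix with
#'   compositions in rows).
#' @param basis An ilr contrast matrix from [ilr_basis].
#' @return Numeric vector of D-1 coordinates (or matrix, rows matching input).
#' @examples
#' ilr(rep(0.2, 5))  # equal parts map to the origin
#' @export
ilr <- function(parts, basis = NULL) {
  if (is.matrix(parts)) {
    if (is.null(basis)) basis <- ilr_basis(ncol(parts))
    bad <- which(parts <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
      cls <- if (!is.null(colnames(parts))) colnames(parts)[bad[1, 2]] else paste("part", bad[1, 2])
      stop("ilr requires strictly positive parts; first offender: row ",
           bad[1, 1], ", ", cls)
    }
    out <- log(parts) %*% t(basis)
    colnames(out) <- rownames(basis)
    return(out)
  }
  if (is.null(basis)) basis <- ilr_basis(length(parts))
  if (length(parts) != ncol(basis))
    stop("composition length does not match basis dimension")
  if (any(parts <= 0)) {
    cls <- if (!is.null(names(parts))) names(parts)[which(parts <= 0)[1]]
           else paste("part", which(parts <= 0)[1])
    stop("ilr requires strictly positive parts; offending class: ", cls)
  }
  drop(basis %*% log(parts))
}

#' Inverse isometric log-ratio transform
#'
#' Maps D-1 ilr coordinates back to the closed strictly positive composition,
#' `close(exp(t(basis) %*% coords))`. Exact inverse of [ilr] under the same
#' basis.
#'
#' @param coords Numeric vector of D-1 coordinates (or matrix with coordinate
#'   vectors in rows).
#' @param basis An ilr contrast matrix from [ilr_basis].
#' @return Closed strictly positive composition (vector or matrix).
#' @examples
#' ilr_inv(c(0, 0, 0, 0))  # origin maps to the uniform composition
#' @export
ilr_inv <- function(coords, basis = NULL) {
  if (is.matrix(coords)) {
    if (is.null(basis)) basis <- ilr_basis(ncol(coords) + 1L)
    if (anyNA(coords) || any(!is.finite(coords)))
      stop("ilr coordinates must be finite")
    lx <- coords %*% basis
    lx <- lx - apply(lx, 1L, max)  # overflow guard; closure removes the shift
    ex <- exp(lx)
    out <- ex / rowSums(ex)
    colnames(out) <- colnames(basis)
    return(out)
  }
  if (is.null(basis)) basis <- ilr_basis(length(coords) + 1L)
  if (anyNA(coords) || any(!is.finite(coords)))
    stop("ilr coordinates must be finite")
  lx <- drop(crossprod(basis, coords))
  lx <- lx - max(lx)
  ex <- exp(lx)
  out <- ex / sum(ex)
  names(out) <- colnames(basis)
  out
}

#' Aitchison distance between two compositions
#'
#' Euclidean distance between centered log-ratio images; equals the Euclidean
#' distance between ilr coordinates for any orthonormal basis.
#'
#' @param x,y Strictly positive compositions of equal length.
#' @return Non-negative distance.
#' @export
aitchison_dist <- function(x, y) {
  if (length(x) != length(y)) stop("compositions must have equal length")
  if (any(x <= 0) || any(y <= 0)) stop("parts must be strictly positive")
  clr <- function(p) log(p) - mean(log(p))
  sqrt(sum((clr(x) - clr(y))^2))
}

#' Write / read an ilr basis as plain text
#'
#' Serializes the contrast matrix to a CSV file so a run's coordinate system
#' is reproducible from its outputs alone.
#'
#' @param basis Contrast matrix from [ilr_basis].
#' @param path File path.
#' @return `read_ilr_basis` returns the matrix; `write_ilr_basis` returns the
#'   path invisibly.
#' @export
write_ilr_basis <- function(basis, path) {
  utils::write.csv(as.data.frame(basis), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_ilr_basis
#' @export
read_ilr_basis <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(d)
}
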