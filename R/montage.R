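#' EEG sensor montage
#'
#' A montage is an ordered set of channel labels with 3-D sensor positions on
#' the unit sphere. It is the geometric basis for spherical-spline channel
#' interpolation and the surface-Laplacian spatial filter.
#'
#' Coordinate convention: x points to the right ear, y to the nasion, z to the
#' vertex; all positions are renormalized to unit Euclidean norm.
#'
#' @param labels character vector of unique channel names.
#' @param positions numeric matrix (n x 3) of sensor positions; each row is
#'   renormalized to the unit sphere.
#' @return An object of class `montage`: list with elements `labels` and
#'   `pos` (n x 3 matrix, rownames = labels).
#' @export
montage <- function(labels, positions) {
  labels <- as.character(labels)
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (length(labels) != nrow(positions))
    stop("label count (", length(labels), ") != position count (",
         nrow(positions), ")")
  if (anyDuplicated(labels))
    stop("duplicate channel label: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (ncol(positions) != 3L)
    stop("positions must have 3 columns")
  if (!all(is.finite(positions)))
    stop("non-finite sensor position")
  nrm <- sqrt(rowSums(positions^2))
  if (any(nrm < 1e-12))
    stop("zero-norm sensor position for channel: ",
         paste(labels[nrm < 1e-12], collapse = ", "))
  positions <- positions / nrm
  rownames(positions) <- labels
  colnames(positions) <- c("x", "y", "z")
  structure(list(labels = labels, pos = positions), class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$labels), " channels: ",
      paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read a montage from an sfp-like text file
#'
#' The file holds whitespace-delimited `label x y z` records. Positions are
#' renormalized to the unit sphere; channel order is preserved.
#'
#' @param path path to the montage file.
#' @return A [montage()].
#' @export
load_montage <- function(path) {
  if (!file.exists(path)) stop("montage file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, col.names = c("label", "x", "y", "z"),
                           colClasses = c("character", rep("numeric", 3)),
                           comment.char = "#", strip.white = TRUE)
  if (nrow(tab) == 0L) stop("empty montage file: ", path)
  montage(tab$label, as.matrix(tab[, c("x", "y", "z")]))
}

#' Write a montage to an sfp-like text file
#'
#' @param mont a [montage()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(mont, path) {
  stopifnot(inherits(mont, "montage"))
  lines <- sprintf("%s\t% .10f\t% .10f\t% .10f", mont$labels,
                   mont$pos[, 1], mont$pos[, 2], mont$pos[, 3])
  writeLines(lines, path)
  invisible(path)
}

# slerp between two unit vectors
.slerp <- function(p, q, f) {
  w <- acos(max(-1, min(1, sum(p * q))))
  if (w < 1e-12) return(p)
  (sin((1 - f) * w) * p + sin(f * w) * q) / sin(w)
}

# point on the nasion-inion midline arc; f = 0 nasion, 0.5 vertex, 1 inion
.midline <- function(f) {
  a <- f * pi
  c(0, cos(a), sin(a))
}

# point on the outer 10% ring (polar angle 72 deg from the vertex);
# az = azimuth in degrees from the nose, positive either hemisphere,
# side = -1 left / +1 right
.ring <- function(az, side) {
  th <- 72 * pi / 180
  ph <- az * pi / 180
  c(side * sin(th) * sin(ph), sin(th) * cos(ph), cos(th))
}

# point on the ear-to-ear central arc at polar angle `deg` from the vertex
.central <- function(deg, side) {
  a <- deg * pi / 180
  c(side * sin(a), 0, cos(a))
}

#' The packaged 30-channel montage
#'
#' Returns the 30 scalp channels used throughout the package (FP1 ... O2)
#' with idealized 10-10 spherical coordinates. The layout is computed
#' analytically: electrodes are placed by spherical interpolation along the
#' nasion-inion midline, the ear-to-ear central arc and the outer 10% ring,
#' with 10%-arc (18 degree) steps, so it is an idealized stand-in for
#' digitized positions. It affects spline constants, not pipeline logic.
#'
#' @return A [montage()] of 30 channels.
#' @export
default_montage <- function() {
  Fz  <- .midline(0.3); FCz <- .midline(0.4); Cz <- .midline(0.5)
  CPz <- .midline(0.6); Pz  <- .midline(0.7); POz <- .midline(0.8)
  pt <- list()
  for (side in c(-1, 1)) {
    s <- if (side < 0) "l" else "r"
    pt[[paste0("FP", s)]] <- .ring(18,  side)
    pt[[paste0("F7",  s)]] <- .ring(54,  side)
    pt[[paste0("FT7", s)]] <- .ring(72,  side)
    pt[[paste0("TP7", s)]] <- .ring(108, side)
    pt[[paste0("P7",  s)]] <- .ring(126, side)
    pt[[paste0("PO7", s)]] <- .ring(144, side)
    pt[[paste0("O1",  s)]] <- .ring(162, side)
    pt[[paste0("C3",  s)]] <- .central(36, side)
    pt[[paste0("F3",  s)]] <- .slerp(Fz,  pt[[paste0("F7", s)]],  0.5)
    pt[[paste0("FC5", s)]] <- .slerp(FCz, pt[[paste0("FT7", s)]], 0.75)
    pt[[paste0("FC1", s)]] <- .slerp(FCz, pt[[paste0("FT7", s)]], 0.25)
    pt[[paste0("CP5", s)]] <- .slerp(CPz, pt[[paste0("TP7", s)]], 0.75)
    pt[[paste0("CP1", s)]] <- .slerp(CPz, pt[[paste0("TP7", s)]], 0.25)
    pt[[paste0("P3",  s)]] <- .slerp(Pz,  pt[[paste0("P7", s)]],  0.5)
    pt[[paste0("PO3", s)]] <- .slerp(POz, pt[[paste0("PO7", s)]], 0.5)
  }
  labels <- c("FP1", "FP2", "F7", "F3", "Fz", "F4", "F8",
              "FC5", "FC1", "FC2", "FC6", "C3", "Cz", "C4",
              "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
              "PO7", "PO3", "POz", "PO4", "PO8", "O1", "O2")
  key <- c(FP1 = "FPl", FP2 = "FPr", F7 = "F7l", F3 = "F3l", F4 = "F3r",
           F8 = "F7r", FC5 = "FC5l", FC1 = "FC1l", FC2 = "FC1r",
           FC6 = "FC5r", C3 = "C3l", C4 = "C3r", CP5 = "CP5l",
           CP1 = "CP1l", CP2 = "CP1r", CP6 = "CP5r", P7 = "P7l",
           P3 = "P3l", P4 = "P3r", P8 = "P7r", PO7 = "PO7l",
           PO3 = "PO3l", PO4 = "PO3r", PO8 = "PO7r", O1 = "O1l",
           O2 = "O1r")
  pos <- matrix(NA_real_, length(labels), 3)
  for (i in seq_along(labels)) {
    lab <- labels[i]
    pos[i, ] <- switch(lab,
                       Fz = Fz, Cz = Cz, Pz = Pz, POz = POz,
                       pt[[key[[lab]]]])
  }
  montage(labels, pos)
}

# matrix of cosines of inter-sensor angles, clipped to [-1, 1]
.cosangles <- function(mont) {
  x <- tcrossprod(mont$pos)
  x[x > 1] <- 1
  x[x < -1] <- -1
  x
}

# angular distances (radians) between all sensors
.angdist <- function(mont) acos(.cosangles(mont))
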