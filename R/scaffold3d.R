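# Idealised G-core scaffolds: four tracts on a cylinder of anchor radius
# `radius` nm, one backbone anchor per guanine position (tract x tetrad
# level). Corners are numbered clockwise viewed from the top; successive
# tetrad levels are rotated by the signed helical twist. These scaffolds
# stand in for MD ensembles only to the extent of the short/long-distance
# dichotomy of propeller paths; absolute path lengths are not calibrated.

#' Build an idealised G-core scaffold
#'
#' @param n_tetrads 2 or 3 stacked tetrads.
#' @param helicity \code{"RH"} or \code{"LH"}; sets the sign of the twist
#'   (counterclockwise per ascending level for RH, viewed from the top).
#' @param rise vertical rise per tetrad, nm (default 0.34).
#' @param twist helical twist per tetrad, degrees (default 30; sign is
#'   taken from \code{helicity}).
#' @param radius anchor radius, nm (default 1.0).
#' @return object of class \code{g4_scaffold}: data.frame of anchors
#'   (\code{corner} 0..3, \code{level} 0-based from the bottom tetrad,
#'   \code{x}, \code{y}, \code{z} in nm) with the geometry parameters as
#'   attributes.
#' @export
build_scaffold <- function(n_tetrads = 3, helicity = c("RH", "LH"),
                           rise = 0.34, twist = 30, radius = 1.0) {
  helicity <- match.arg(helicity)
  stopifnot(n_tetrads %in% c(2, 3))
  if (rise <= 0 || twist <= 0 || radius <= 0) {
    stop("geometry parameters must be positive")
  }
  tw <- (if (helicity == "RH") 1 else -1) * twist * pi / 180
  grid <- expand.grid(level = 0:(n_tetrads - 1L), corner = 0:3)
  theta <- -grid$corner * pi / 2 + grid$level * tw
  anchors <- data.frame(
    corner = grid$corner, level = grid$level,
    x = radius * cos(theta), y = radius * sin(theta),
    z = grid$level * rise
  )
  structure(anchors, class = c("g4_scaffold", "data.frame"),
            n_tetrads = as.integer(n_tetrads), helicity = helicity,
            rise = rise, twist = twist, radius = radius)
}

scaffold_anchor <- function(scaffold, corner, level) {
  i <- which(scaffold$corner == corner & scaffold$level == level)
  stopifnot(length(i) == 1L)
  unlist(scaffold[i, c("x", "y", "z")], use.names = TRUE)
}

#' Attachment points of a propeller loop on a scaffold
#'
#' A propeller loop leaves the exit end of tract k and enters tract k+1 at
#' the opposite tetrad level. The mandated winding of the connecting path
#' is the loop's sign direction (clockwise for \code{+p}).
#'
#' @param scaffold a \code{g4_scaffold}.
#' @param trace a \code{g4_trace} from [trace_topology()].
#' @param position loop position, \code{"I"}, \code{"II"} or \code{"III"}
#'   (or 1..3).
#' @return list with points \code{a}, \code{b} (named xyz vectors, nm) and
#'   \code{winding} (\code{"clockwise"}/\code{"counterclockwise"}).
#' @export
loop_attachment_pair <- function(scaffold, trace, position) {
  stopifnot(inherits(trace, "g4_trace"))
  k <- if (is.character(position)) match(position, c("I", "II", "III"))
       else as.integer(position)
  stopifnot(!is.na(k), k %in% 1:3)
  if (!is_propeller(trace$tokens[k])) {
    stop("loop at position ", c("I", "II", "III")[k], " is ",
         loop_kind(trace$tokens[k]), ", not a propeller")
  }
  top <- attr(scaffold, "n_tetrads") - 1L
  lev_a <- if (trace$directions[k] == "up") top else 0L
  lev_b <- top - lev_a
  list(
    a = scaffold_anchor(scaffold, trace$corners[k], lev_a),
    b = scaffold_anchor(scaffold, trace$corners[k + 1], lev_b),
    winding = if (loop_sign(trace$tokens[k]) == "+") "clockwise"
              else "counterclockwise"
  )
}

#' Shortest surface path between two anchors, winding one way
#'
#' Geodesic on the guard cylinder (anchor radius plus a probe offset) from
#' \code{a} to \code{b}, constrained to wind only in the given direction:
#' length \eqn{\sqrt{\Delta z^2 + (r \Delta\phi)^2}} with \eqn{\Delta\phi}
#' the azimuthal span traversed in that direction. Clockwise is the
#' negative azimuthal direction viewed from the top (+z).
#'
#' @param scaffold a \code{g4_scaffold} (supplies radius and probe frame).
#' @param a,b xyz points (nm), away from the core axis.
#' @param direction winding direction of the path.
#' @param probe radial offset of the guard cylinder above the anchor
#'   radius, nm (default 0.2).
#' @param n_points vertices of the returned polyline.
#' @return object of class \code{g4_path}: list with \code{points}
#'   (n x 3 matrix on the guard cylinder), \code{length} (nm) and
#'   \code{winding}.
#' @export
shortest_surface_path <- function(scaffold, a, b,
                                  direction = c("counterclockwise",
                                                "clockwise"),
                                  probe = 0.2, n_points = 33) {
  direction <- match.arg(direction)
  stopifnot(length(a) == 3L, length(b) == 3L)
  r <- attr(scaffold, "radius") + probe
  if (all(abs(a - b) < 1e-12)) {
    return(structure(list(points = rbind(a, b), length = 0,
                          winding = direction), class = "g4_path"))
  }
  if (max(abs(a[1:2])) < 1e-12 || max(abs(b[1:2])) < 1e-12) {
    stop("endpoints must lie off the core axis")
  }
  phi_a <- atan2(a[2], a[1])
  phi_b <- atan2(b[2], b[1])
  dphi <- if (direction == "counterclockwise") (phi_b - phi_a) %% (2 * pi)
          else (phi_a - phi_b) %% (2 * pi)
  sgn <- if (direction == "counterclockwise") 1 else -1
  t <- seq(0, 1, length.out = n_points)
  phi <- phi_a + sgn * dphi * t
  z <- a[3] + (b[3] - a[3]) * t
  pts <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  structure(
    list(points = pts,
         length = sqrt((b[3] - a[3])^2 + (r * dphi)^2),
         winding = direction),
    class = "g4_path"
  )
}

#' Propeller surface-path lengths over the topology landscape
#'
#' Evaluates, for every valid topology and both helicities (or a chosen
#' one), the constrained surface path of each propeller loop on the default
#' scaffold, together with its short/long-distance label from the
#' closed-form rule.
#'
#' @param helicity \code{"RH"}, \code{"LH"} or both (default).
#' @param n_tetrads scaffold tetrad count.
#' @param probe guard-cylinder probe offset, nm.
#' @param ... further geometry arguments passed to [build_scaffold()].
#' @return data.frame: \code{topology}, \code{helicity}, \code{position},
#'   \code{geometry_label}, \code{path_length_nm}.
#' @export
propeller_path_lengths <- function(helicity = c("RH", "LH"), n_tetrads = 3,
                                   probe = 0.2, ...) {
  helicity <- match.arg(helicity, several.ok = TRUE)
  rows <- list()
  for (h in helicity) {
    scaffold <- build_scaffold(n_tetrads = n_tetrads, helicity = h, ...)
    for (topo in enumerate_topologies()) {
      tr <- trace_topology(topo)
      labels <- classify_propellers_rule(topo, h)
      for (k in which(is_propeller(tr$tokens))) {
        ap <- loop_attachment_pair(scaffold, tr, k)
        path <- shortest_surface_path(scaffold, ap$a, ap$b, ap$winding,
                                      probe = probe)
        rows[[length(rows) + 1L]] <- data.frame(
          topology = topo, helicity = h,
          position = c("I", "II", "III")[k],
          geometry_label = labels[k],
          path_length_nm = path$length, stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' RMSD after optimal rigid superposition (Kabsch)
#'
#' Superposes \code{coordsB} onto \code{coordsA} by the optimal proper
#' rotation and translation (no reflection) and returns the residual RMSD.
#'
#' @param coordsA,coordsB n x 3 matrices of matched points, n >= 3.
#' @return RMSD in the input length unit.
#' @export
kabsch_rmsd <- function(coordsA, coordsB) {
  A <- as.matrix(coordsA); B <- as.matrix(coordsB)
  if (!all(dim(A) == dim(B))) stop("coordinate sets differ in size")
  if (nrow(A) < 3L || ncol(A) != 3L) stop("need at least 3 points in 3D")
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(B0, A0))           # covariance of B onto A
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Bfit <- B0 %*% t(R)
  sqrt(mean(rowSums((A0 - Bfit)^2)))
}

#' Write a scaffold as a pseudo-atom PDB file
#'
#' Anchors are written as one pseudo-atom per guanine position (element
#' name C4', residue DG), one chain per tract (A-D), residue number =
#' tetrad level + 1. Coordinates are converted from nm to Angstrom, the
#' PDB convention.
#'
#' @param scaffold a \code{g4_scaffold}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_scaffold_pdb <- function(scaffold, path) {
  stopifnot(inherits(scaffold, "g4_scaffold"))
  n <- nrow(scaffold)
  xyz <- as.numeric(t(as.matrix(scaffold[, c("x", "y", "z")]) * 10))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = rep("ATOM", n),
    eleno = seq_len(n),
    elety = rep("C4'", n),
    resid = rep("DG", n),
    chain = LETTERS[scaffold$corner + 1L],
    resno = scaffold$level + 1L,
    o = rep(1, n), b = rep(0, n)
  )
  invisible(path)
}

#' Read a pseudo-atom scaffold PDB back into coordinates
#'
#' @param path PDB file written by [write_scaffold_pdb()].
#' @return data.frame with \code{corner}, \code{level}, \code{x}, \code{y},
#'   \code{z} (nm).
#' @export
read_scaffold_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  data.frame(
    corner = match(at$chain, LETTERS) - 1L,
    level = at$resno - 1L,
    x = at$x / 10, y = at$y / 10, z = at$z / 10
  )
}
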