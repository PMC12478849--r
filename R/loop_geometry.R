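# Propeller loops come in two geometries. Whether a given propeller is
# short-distance (SD, attachment points nearly above one another) or
# long-distance (LD, attachment points separated by most of a helical turn)
# is fixed by the topology and the helicity: the tilt of the G-tracts either
# absorbs or adds to the quarter-turn the loop must make around the core.

#' Classify propeller loops as short- or long-distance (closed-form rule)
#'
#' Under right-handed helicity a \code{+p} loop is long-distance when zero
#' or two nonpropeller loops precede it in the sequence (5' to 3'), and a
#' \code{-p} loop is long-distance when exactly one nonpropeller loop
#' precedes it. Left-handed helicity swaps the two conditions. Lateral and
#' diagonal loops get \code{NA}.
#'
#' @param topology topology string or token triple.
#' @param helicity \code{"RH"} or \code{"LH"}.
#' @return character vector of length 3 with values \code{"SD"},
#'   \code{"LD"} or \code{NA}.
#' @export
classify_propellers_rule <- function(topology, helicity = c("RH", "LH")) {
  helicity <- match.arg(helicity)
  tokens <- as_loop_tokens(topology)
  prop <- is_propeller(tokens)
  out <- rep(NA_character_, 3L)
  for (k in which(prop)) {
    n_pre <- sum(!prop[seq_len(k - 1L)])
    ld_rh <- if (loop_sign(tokens[k]) == "+") n_pre %in% c(0L, 2L)
             else n_pre == 1L
    ld <- if (helicity == "RH") ld_rh else !ld_rh
    out[k] <- if (ld) "LD" else "SD"
  }
  out
}

#' Count long-distance propeller loops in a topology
#'
#' @inheritParams classify_propellers_rule
#' @return integer in 0..3.
#' @export
count_long_distance <- function(topology, helicity = c("RH", "LH")) {
  sum(classify_propellers_rule(topology, helicity) == "LD", na.rm = TRUE)
}

#' Long-distance census over all valid topologies
#'
#' @param helicity \code{"RH"} or \code{"LH"}.
#' @return data.frame with one row per valid topology: \code{topology},
#'   \code{helicity}, \code{ld_count}, \code{has_ld}, and the per-position
#'   geometry labels \code{geometry_I}, \code{geometry_II},
#'   \code{geometry_III}.
#' @export
propeller_census <- function(helicity = c("RH", "LH")) {
  helicity <- match.arg(helicity)
  topologies <- enumerate_topologies()
  labels <- t(vapply(topologies, classify_propellers_rule, character(3),
                     helicity = helicity))
  data.frame(
    topology = topologies,
    helicity = helicity,
    ld_count = rowSums(labels == "LD", na.rm = TRUE),
    has_ld = rowSums(labels == "LD", na.rm = TRUE) > 0,
    geometry_I = labels[, 1], geometry_II = labels[, 2],
    geometry_III = labels[, 3],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Unwrap a topology into a 2D projection
#'
#' Cuts the G-core cylinder and unrolls it so the four tracts appear as
#' tilted columns in strand order. The unwrap proceeds clockwise or
#' counterclockwise according to the directionality of the first signed
#' loop, which also places the 5' end on the right or left edge of the
#' drawing, respectively. The tract tilt encodes helicity: each tetrad
#' level is displaced along the unwrap coordinate by the helical twist.
#' Each loop is assigned its two attachment points in the plane; for a
#' propeller the end tract is taken at the periodic image consistent with
#' the loop's mandated winding direction, so the in-plane attachment
#' distance reflects the arc the loop actually traverses.
#'
#' @param topology topology string or token triple.
#' @param helicity \code{"RH"} or \code{"LH"}.
#' @param n_tetrads number of tetrads in the drawn core (default 3).
#' @param tract_spacing horizontal spacing between adjacent corners, in
#'   arbitrary plane units (quarter turn = 1 spacing).
#' @param tilt per-level displacement of a tract along the unwrap
#'   coordinate, in tract-spacing units.
#' @param level_spacing vertical spacing between tetrad levels, in
#'   tract-spacing units.
#' @return object of class \code{g4_projection}: list with \code{tracts}
#'   (tract, corner, x, x_plot, direction), \code{loops} (position, token,
#'   kind, attachment coordinates and in-plane \code{distance}),
#'   \code{unwrap} direction and the layout parameters.
#' @export
unwrap_projection <- function(topology, helicity = c("RH", "LH"),
                              n_tetrads = 3, tract_spacing = 1.0,
                              tilt = 0.35, level_spacing = 0.5) {
  helicity <- match.arg(helicity)
  tr <- trace_topology(topology)
  tokens <- tr$tokens
  signs <- loop_sign(tokens)
  first_signed <- signs[!is.na(signs)][1]
  if (is.na(first_signed)) first_signed <- "-"  # unreachable for valid forms
  unwrap <- if (first_signed == "-") "counterclockwise" else "clockwise"

  # Angular step of each loop measured along the unwrap direction, in
  # quarter turns (always positive: tracts advance left to right).
  step_units <- vapply(tokens, function(tok) {
    if (tok == "d") return(2)
    same <- (loop_sign(tok) == "-") == (unwrap == "counterclockwise")
    if (same) 1 else 3
  }, numeric(1))
  u <- cumsum(c(0, step_units)) * tract_spacing

  # Helical twist displaces higher tetrad levels counterclockwise (RH) or
  # clockwise (LH) viewed from the top; expressed in unwrap-x units.
  tilt_x <- tilt * tract_spacing *
    (if (helicity == "RH") 1 else -1) *
    (if (unwrap == "counterclockwise") 1 else -1)

  top <- n_tetrads - 1L
  exit_level <- ifelse(tr$directions == "up", top, 0L)

  loops <- lapply(1:3, function(k) {
    lev_a <- exit_level[k]
    lev_b <- if (is_propeller(tokens[k])) top - lev_a else lev_a
    # End-tract image consistent with the physical winding: a loop drawn
    # against the unwrap direction (step 3) really winds one quarter turn
    # the other way, i.e. at the image one full turn to the left.
    x_base_b <- if (step_units[k] == 3) u[k + 1] - 4 * tract_spacing
                else u[k + 1]
    a <- c(u[k] + tilt_x * lev_a, lev_a * level_spacing * tract_spacing)
    b <- c(x_base_b + tilt_x * lev_b, lev_b * level_spacing * tract_spacing)
    data.frame(position = c("I", "II", "III")[k], token = tokens[k],
               kind = loop_kind(tokens[k]),
               x_a = a[1], z_a = a[2], x_b = b[1], z_b = b[2],
               distance = sqrt(sum((a - b)^2)),
               stringsAsFactors = FALSE)
  })
  loops <- do.call(rbind, loops)

  tracts <- data.frame(
    tract = 1:4, corner = tr$corners, x = u,
    x_plot = if (unwrap == "clockwise") -u else u,
    direction = tr$directions, stringsAsFactors = FALSE
  )
  structure(
    list(topology = format_topology(tokens), helicity = helicity,
         unwrap = unwrap, tracts = tracts, loops = loops,
         params = list(n_tetrads = n_tetrads, tract_spacing = tract_spacing,
                       tilt = tilt, level_spacing = level_spacing)),
    class = "g4_projection"
  )
}

#' Threshold separating short- and long-distance attachment distances
#'
#' Collects the in-plane propeller attachment distances over all 26 valid
#' topologies under both helicities at the given layout constants, and
#' returns the midpoint of the widest gap in that distance distribution.
#' The two geometric populations are disjoint at the default layout, so
#' this midpoint separates them; the attribute \code{band} records the
#' admissible interval (largest distance below, smallest above).
#'
#' @inheritParams unwrap_projection
#' @return numeric threshold with attribute \code{band}.
#' @export
ld_distance_threshold <- function(n_tetrads = 3, tract_spacing = 1.0,
                                  tilt = 0.35, level_spacing = 0.5) {
  d <- unlist(lapply(enumerate_topologies(), function(topo) {
    lapply(c("RH", "LH"), function(h) {
      pr <- unwrap_projection(topo, h, n_tetrads = n_tetrads,
                              tract_spacing = tract_spacing, tilt = tilt,
                              level_spacing = level_spacing)
      pr$loops$distance[pr$loops$kind == "propeller"]
    })
  }))
  d <- sort(unique(round(d, 12)))
  if (length(d) < 2L) stop("degenerate layout: all distances equal")
  gaps <- diff(d)
  i <- which.max(gaps)
  structure((d[i] + d[i + 1]) / 2, band = c(low = d[i], high = d[i + 1]))
}

#' Classify propeller loops from a 2D projection
#'
#' Geometric counterpart of [classify_propellers_rule()]: a propeller is
#' long-distance when its in-plane attachment distance exceeds the
#' threshold. Lateral and diagonal loops get \code{NA}.
#'
#' @param projection a \code{g4_projection} from [unwrap_projection()].
#' @param threshold plane distance; default the widest-gap midpoint from
#'   [ld_distance_threshold()] at the projection's layout constants.
#' @return character vector of length 3 with \code{"SD"}/\code{"LD"}/NA.
#' @export
classify_propellers_geometric <- function(projection, threshold = NULL) {
  stopifnot(inherits(projection, "g4_projection"))
  if (is.null(threshold)) {
    p <- projection$params
    threshold <- ld_distance_threshold(p$n_tetrads, p$tract_spacing,
                                       p$tilt, p$level_spacing)
  }
  with(projection$loops,
       ifelse(kind != "propeller", NA_character_,
              ifelse(distance > threshold, "LD", "SD")))
}
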