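# Canonical loop-type vocabulary. A unimolecular G4 has three loops, each of
# one of five types: propeller (p) and lateral (l) loops carry a sign giving
# the clockwise (+) or anticlockwise (-) progression of the strand viewed
# from the top of the G-core; the diagonal loop (d) is unsigned. Token order
# below is the canonical sort order used for enumeration output.
LOOP_TOKENS <- c("-l", "-p", "+l", "+p", "d")

loop_kind <- function(tokens) {
  kinds <- c(p = "propeller", l = "lateral", d = "diagonal")
  unname(kinds[substr(tokens, nchar(tokens), nchar(tokens))])
}

loop_sign <- function(tokens) {
  ifelse(tokens == "d", NA_character_, substr(tokens, 1L, 1L))
}

is_propeller <- function(tokens) loop_kind(tokens) == "propeller"

# Corner step of each loop type on the square cross-section, with "+" defined
# as a clockwise step viewed from the top (corner indices increase clockwise).
loop_step <- function(tokens) {
  steps <- c("+p" = 1L, "+l" = 1L, "-p" = -1L, "-l" = -1L, "d" = 2L)
  unname(steps[tokens])
}

normalize_topology_text <- function(text) {
  # Unicode minus (U+2212) and en dash (U+2013) are common in the literature;
  # both map to ASCII '-' before parsing.
  text <- gsub("−", "-", text, fixed = TRUE)
  gsub("–", "-", text, fixed = TRUE)
}

#' Parse a looping-topology string
#'
#' A topology is written as three concatenated loop tokens in strand order
#' (positions I, II, III), e.g. \code{"-pd+l"}: a \code{-p} propeller, a
#' diagonal, then a \code{+l} lateral loop. Unicode minus and en dash are
#' accepted and normalised to ASCII \code{-}.
#'
#' @param text single topology string, e.g. \code{"-pd+p"}.
#' @return character vector of three canonical loop tokens.
#' @examples
#' parse_topology("-pd+l")
#' @export
parse_topology <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- normalize_topology_text(text)
  m <- gregexpr("([+-][pl])|d|(.)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  bad <- tokens[!tokens %in% LOOP_TOKENS]
  if (length(bad) > 0L) {
    stop("malformed loop token(s): ", paste(sQuote(bad), collapse = ", "),
         " in ", sQuote(text))
  }
  if (length(tokens) != 3L) {
    stop("a topology needs exactly 3 loop tokens, got ", length(tokens),
         " in ", sQuote(text))
  }
  tokens
}

#' Format loop tokens as a canonical topology string
#'
#' @param tokens character vector of three loop tokens.
#' @return single ASCII topology string.
#' @export
format_topology <- function(tokens) {
  tokens <- as_loop_tokens(tokens)
  paste0(tokens, collapse = "")
}

# Accept either a topology string or a 3-token vector.
as_loop_tokens <- function(topology) {
  if (length(topology) == 1L && !topology %in% LOOP_TOKENS) {
    return(parse_topology(topology))
  }
  stopifnot(length(topology) == 3L, all(topology %in% LOOP_TOKENS))
  as.character(topology)
}

#' Trace the strand walk of a topology over the G-core
#'
#' Walks the four G-tracts implied by the three loops, starting at corner 0
#' with the first tract running up. Propeller loops connect the top and
#' bottom tetrads of adjacent tracts, so the tract direction repeats and the
#' loop spans the core; lateral and diagonal loops connect guanines within
#' one tetrad, so they stay on the face where the previous tract exits and
#' flip the direction of the next tract. Corner indices increase clockwise
#' viewed from the top; \code{+} loops step +1 corner, \code{-} loops -1,
#' diagonal loops +2 (mod 4).
#'
#' @param topology topology string or token triple.
#' @return list with \code{tokens}, \code{corners} (4 values in 0..3),
#'   \code{directions} (4 values \code{"up"}/\code{"down"}) and
#'   \code{loop_faces} (3 values \code{"top"}/\code{"bottom"}/
#'   \code{"spanning"}).
#' @export
trace_topology <- function(topology) {
  tokens <- as_loop_tokens(topology)
  corners <- integer(4)
  directions <- character(4)
  faces <- character(3)
  corner <- 0L
  dir <- "up"
  corners[1] <- corner
  directions[1] <- dir
  for (k in 1:3) {
    if (is_propeller(tokens[k])) {
      faces[k] <- "spanning"
      # direction unchanged: propellers join tracts in parallel
    } else {
      faces[k] <- if (dir == "up") "top" else "bottom"
      dir <- if (dir == "up") "down" else "up"
    }
    corner <- (corner + loop_step(tokens[k])) %% 4L
    corners[k + 1] <- corner
    directions[k + 1] <- dir
  }
  structure(
    list(tokens = tokens, corners = corners, directions = directions,
         loop_faces = faces),
    class = "g4_trace"
  )
}

#' Is a loop triple a valid looping topology?
#'
#' Valid topologies are those whose strand walk (i) visits all four corners
#' of the G-core exactly once (G-tract continuity) and (ii) places no two
#' diagonal loops on the same tetrad face.
#'
#' @param topology topology string or token triple.
#' @return logical scalar.
#' @export
is_valid_topology <- function(topology) {
  tr <- trace_topology(topology)
  if (anyDuplicated(tr$corners) > 0L) return(FALSE)
  diag_faces <- tr$loop_faces[loop_kind(tr$tokens) == "diagonal"]
  anyDuplicated(diag_faces) == 0L
}

#' Enumerate all valid looping topologies
#'
#' Filters all 5^3 = 125 loop triples by [is_valid_topology()]; yields the
#' 26 standard unimolecular G4 topologies. Order is lexicographic over loop
#' tokens with token order \code{-l < -p < +l < +p < d} (frozen for
#' reproducibility).
#'
#' @return character vector of 26 canonical topology strings.
#' @export
enumerate_topologies <- function() {
  grid <- expand.grid(III = LOOP_TOKENS, II = LOOP_TOKENS, I = LOOP_TOKENS,
                      stringsAsFactors = FALSE)
  triples <- Map(c, grid$I, grid$II, grid$III)
  keep <- vapply(triples, is_valid_topology, logical(1))
  topo <- vapply(triples[keep], format_topology, character(1))
  rank <- function(tok) match(tok, LOOP_TOKENS)
  toks <- t(vapply(triples[keep], rank, integer(3)))
  unname(topo[order(toks[, 1], toks[, 2], toks[, 3])])
}

#' Enumerate tetrad polarity patterns
#'
#' Each G-tetrad has one of two hydrogen-bond polarities, left (LP) or right
#' (RP). A pattern assigns one polarity per tetrad, ordered bottom to top.
#'
#' @param n_tetrads number of tetrads (>= 1).
#' @return character vector of \code{2^n_tetrads} patterns such as
#'   \code{"LP-RP-LP"}; the bottom tetrad varies fastest.
#' @export
enumerate_polarity_patterns <- function(n_tetrads) {
  stopifnot(is.numeric(n_tetrads), length(n_tetrads) == 1L)
  if (n_tetrads < 1) stop("n_tetrads must be >= 1")
  grid <- do.call(expand.grid,
                  c(rep(list(c("LP", "RP")), n_tetrads),
                    stringsAsFactors = FALSE))
  apply(grid, 1L, paste, collapse = "-")
}

#' Enumerate the conformational grid
#'
#' Builds the full Cartesian grid of conformations: topology x polarity
#' pattern x loop-length triple at a fixed helicity and tetrad count. With
#' the default loop-length range 1..4 this is the grid spanned by sequences
#' G3TiG3TjG3TkG3 (three tetrads) or G2TiG2TjG2TkG2 (two tetrads) with
#' i, j, k varied independently from 1 to 4: 13,312 three-tetrad or 6,656
#' two-tetrad conformations.
#'
#' @param n_tetrads 2 or 3.
#' @param loop_length_range integer vector of admissible per-loop lengths
#'   (nt), default \code{1:4}.
#' @param helicity \code{"RH"} or \code{"LH"}.
#' @param topologies optional subset of topology strings; default all 26.
#' @return data.frame with columns \code{conformation_id}, \code{n_tetrads},
#'   \code{helicity}, \code{topology}, \code{polarity}, \code{len_I},
#'   \code{len_II}, \code{len_III}.
#' @export
enumerate_conformations <- function(n_tetrads = 3,
                                    loop_length_range = 1:4,
                                    helicity = c("RH", "LH"),
                                    topologies = NULL) {
  helicity <- match.arg(helicity)
  stopifnot(n_tetrads %in% c(2, 3))
  lens <- sort(unique(as.integer(loop_length_range)))
  if (length(lens) == 0L) stop("empty loop_length_range")
  if (any(lens < 1L)) stop("loop lengths must be >= 1")
  if (is.null(topologies)) topologies <- enumerate_topologies()
  stopifnot(all(vapply(topologies, is_valid_topology, logical(1))))
  pol <- enumerate_polarity_patterns(n_tetrads)
  grid <- expand.grid(len_III = lens, len_II = lens, len_I = lens,
                      polarity = pol, topology = topologies,
                      stringsAsFactors = FALSE)
  out <- data.frame(
    n_tetrads = as.integer(n_tetrads),
    helicity = helicity,
    topology = grid$topology,
    polarity = grid$polarity,
    len_I = grid$len_I,
    len_II = grid$len_II,
    len_III = grid$len_III,
    stringsAsFactors = FALSE
  )
  out <- out[order(match(out$topology, topologies), out$polarity,
                   out$len_I, out$len_II, out$len_III), , drop = FALSE]
  rownames(out) <- NULL
  out <- cbind(conformation_id = conformation_id(out), out,
               stringsAsFactors = FALSE)
  out$conformation_id <- as.character(out$conformation_id)
  out
}

#' Stable conformation identifier
#'
#' @param conformations data.frame with the grid columns of
#'   [enumerate_conformations()].
#' @return character vector of unique ids such as
#'   \code{"3T-RH_-pd+p_LP-RP-LP_1-3-1"}.
#' @export
conformation_id <- function(conformations) {
  sprintf("%dT-%s_%s_%s_%d-%d-%d",
          conformations$n_tetrads, conformations$helicity,
          conformations$topology, conformations$polarity,
          conformations$len_I, conformations$len_II, conformations$len_III)
}

#' G4 class label of a conformation batch
#'
#' Conformations are grouped into validation classes by tetrad count and
#' helicity, e.g. \code{"3T-RH"}; RMSD thresholds are per class.
#'
#' @param conformations data.frame with \code{n_tetrads} and \code{helicity}.
#' @return character vector of class labels.
#' @export
conformation_class <- function(conformations) {
  sprintf("%dT-%s", conformations$n_tetrads, conformations$helicity)
}
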