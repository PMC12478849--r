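# Synthetic foldability data. The generator emulates the statistical
# structure of a steered-MD foldability screen over the conformational
# grid: each conformation folds with a probability set by its geometry
# (long-distance propellers and hard loop-length violations penalise the
# log-odds; longer loops help), a small label-noise rate decouples the
# recorded outcome from the structural one, and an RMSD value is emitted
# from a class-conditional truncated normal so that downstream RMSD
# thresholding can re-derive the labels. It is synthetic by construction:
# it reproduces the qualitative trends the analysis assumes, not MD
# energetics.

#' Generative parameters for synthetic foldability data
#'
#' Effects are additive on the log-odds scale. The long-distance propeller
#' penalty follows a relief schedule \code{ld_penalty_offset +
#' ld_penalty_scale / min(L, ld_floor_nt)}: harshest at 1 nt, shrinking
#' with loop length L and constant from the floor (5 nt) on. Diagonal
#' loops below 3 nt and lateral loops below 2 nt incur the hard-violation
#' penalty. RMSD values are emitted from truncated normals (lower bound 0).
#'
#' @param base_logodds baseline log-odds of folding.
#' @param length_benefit log-odds gain per nt of total loop length.
#' @param length_benefit_cap total loop length (nt) beyond which the
#'   benefit saturates.
#' @param ld_penalty_scale,ld_penalty_offset,ld_floor_nt long-distance
#'   propeller penalty schedule (per LD loop).
#' @param violation_penalty log-odds penalty per hard loop-length
#'   violation.
#' @param noise_rate probability that the recorded outcome differs from
#'   the structural one.
#' @param rmsd_folded_mean,rmsd_folded_sd folded-state RMSD emission (nm).
#' @param rmsd_misfolded_mean,rmsd_misfolded_sd misfolded-state RMSD
#'   emission (nm).
#' @return object of class \code{g4_sim_params}.
#' @export
g4_sim_params <- function(base_logodds = 0.3,
                          length_benefit = 0.3,
                          length_benefit_cap = 12,
                          ld_penalty_scale = 5.2,
                          ld_penalty_offset = 1.3,
                          ld_floor_nt = 5,
                          violation_penalty = 8,
                          noise_rate = 0.05,
                          rmsd_folded_mean = 0.06,
                          rmsd_folded_sd = 0.015,
                          rmsd_misfolded_mean = 0.20,
                          rmsd_misfolded_sd = 0.05) {
  p <- list(base_logodds = base_logodds, length_benefit = length_benefit,
            length_benefit_cap = length_benefit_cap,
            ld_penalty_scale = ld_penalty_scale,
            ld_penalty_offset = ld_penalty_offset,
            ld_floor_nt = ld_floor_nt,
            violation_penalty = violation_penalty,
            noise_rate = noise_rate,
            rmsd_folded_mean = rmsd_folded_mean,
            rmsd_folded_sd = rmsd_folded_sd,
            rmsd_misfolded_mean = rmsd_misfolded_mean,
            rmsd_misfolded_sd = rmsd_misfolded_sd)
  if (p$noise_rate < 0 || p$noise_rate > 1) stop("noise_rate must be in [0, 1]")
  if (p$rmsd_folded_mean >= p$rmsd_misfolded_mean) {
    stop("folded RMSD mean must be below misfolded RMSD mean")
  }
  if (p$rmsd_folded_sd <= 0 || p$rmsd_misfolded_sd <= 0) {
    stop("RMSD emission sds must be positive")
  }
  if (p$ld_floor_nt < 1) stop("ld_floor_nt must be >= 1")
  structure(p, class = "g4_sim_params")
}

#' @rdname g4_sim_params
#' @param params a \code{g4_sim_params} object.
#' @param path optional file path for the JSON.
#' @export
sim_params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "g4_sim_params"))
  js <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname g4_sim_params
#' @param json JSON string or file path.
#' @export
sim_params_from_json <- function(json) {
  do.call(g4_sim_params, jsonlite::fromJSON(json))
}

ld_length_penalty <- function(length_nt, params) {
  params$ld_penalty_offset +
    params$ld_penalty_scale / pmin(length_nt, params$ld_floor_nt)
}

# Truncated-normal (lower bound 0) quantile and inverse-CDF sampler.
truncnorm_quantile <- function(p, mean, sd, lower = 0) {
  p0 <- stats::pnorm((lower - mean) / sd)
  mean + sd * stats::qnorm(p0 + p * (1 - p0))
}

#' Fold log-odds of conformations under the generative model
#'
#' @param conformations conformational-grid data.frame.
#' @param params a \code{g4_sim_params} object.
#' @return numeric vector of log-odds.
#' @export
fold_logodds <- function(conformations, params = g4_sim_params()) {
  lens <- as.matrix(conformations[, c("len_I", "len_II", "len_III")])
  total <- rowSums(lens)
  logodds <- params$base_logodds +
    params$length_benefit * pmin(total, params$length_benefit_cap)
  key <- paste(conformations$topology, conformations$helicity)
  for (ku in unique(key)) {
    sel <- key == ku
    parts <- strsplit(ku, " ", fixed = TRUE)[[1]]
    tokens <- as_loop_tokens(parts[1])
    g <- classify_propellers_rule(tokens, parts[2])
    kinds <- loop_kind(tokens)
    for (k in 1:3) {
      L <- lens[sel, k]
      if (!is.na(g[k]) && g[k] == "LD") {
        logodds[sel] <- logodds[sel] - ld_length_penalty(L, params)
      }
      if (kinds[k] == "diagonal") {
        logodds[sel] <- logodds[sel] - params$violation_penalty * (L < 3)
      } else if (kinds[k] == "lateral") {
        logodds[sel] <- logodds[sel] - params$violation_penalty * (L < 2)
      }
    }
  }
  logodds
}

# Small deterministic string hash (31-adic, mod 2^31 - 1) used to derive
# per-conformation RNG streams, so any subset of the grid reproduces the
# same records for a given global seed.
string_hash <- function(s) {
  vapply(s, function(si) {
    h <- 0
    for (c in utf8ToInt(si)) h <- (h * 31 + c) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

#' Generate synthetic foldability records over a conformational grid
#'
#' For each conformation the structural outcome is drawn from the logistic
#' model of [fold_logodds()], the recorded outcome is flipped with
#' probability \code{noise_rate} (label noise: the stored \code{true}
#' label keeps the structural outcome while the RMSD is emitted from the
#' flipped state), and an RMSD value is drawn from the class-conditional
#' truncated-normal emission.
#'
#' @param conformations grid from [enumerate_conformations()].
#' @param params a \code{g4_sim_params} object.
#' @param seed global seed; per-conformation streams are derived by
#'   hashing the conformation id, so subsets are reproducible.
#' @return \code{conformations} with added columns \code{p_fold},
#'   \code{true_foldable} (structural outcome), \code{emission_foldable}
#'   (state whose RMSD emission was used) and \code{rmsd_nm}.
#' @export
generate_records <- function(conformations, params = g4_sim_params(),
                             seed = 1) {
  stopifnot(inherits(params, "g4_sim_params"))
  p_fold <- stats::plogis(fold_logodds(conformations, params))
  if (any(!is.finite(p_fold)) || any(p_fold < 0 | p_fold > 1)) {
    stop("invalid fold probabilities")
  }
  h <- string_hash(conformations$conformation_id)
  n <- nrow(conformations)
  u <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    set.seed((as.numeric(seed) + h[i]) %% 2147483647)
    u[i, ] <- stats::runif(3)
  }
  true_foldable <- u[, 1] < p_fold
  emission_foldable <- ifelse(u[, 2] < params$noise_rate,
                              !true_foldable, true_foldable)
  rmsd <- ifelse(
    emission_foldable,
    truncnorm_quantile(u[, 3], params$rmsd_folded_mean,
                       params$rmsd_folded_sd),
    truncnorm_quantile(u[, 3], params$rmsd_misfolded_mean,
                       params$rmsd_misfolded_sd)
  )
  out <- conformations
  out$p_fold <- p_fold
  out$true_foldable <- true_foldable
  out$emission_foldable <- emission_foldable
  out$rmsd_nm <- rmsd
  out
}

#' Sample a folded-state RMSD fluctuation trace
#'
#' I.i.d. draws from the folded-state truncated-normal emission; used to
#' exercise percentile thresholding the way reference MD fluctuation
#' traces are used.
#'
#' @param class G4 class label (kept for interface symmetry; all classes
#'   share the folded emission parameters).
#' @param n number of draws (>= 1).
#' @param params a \code{g4_sim_params} object.
#' @param seed RNG seed.
#' @return numeric vector of RMSD values (nm), all nonnegative.
#' @export
generate_folded_rmsd_trace <- function(class = c("3T-RH", "2T-RH", "2T-LH"),
                                       n, params = g4_sim_params(),
                                       seed = 1) {
  class <- match.arg(class)
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  truncnorm_quantile(stats::runif(n), params$rmsd_folded_mean,
                     params$rmsd_folded_sd)
}
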