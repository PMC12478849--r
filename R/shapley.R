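# Exact Shapley attribution by coalition enumeration. With at most a dozen
# grouped features the 2^n coalition values can be evaluated exhaustively,
# so attributions satisfy the Shapley axioms (efficiency, symmetry, dummy)
# exactly rather than approximately as in sampling-based SHAP estimators.

#' Exact Shapley values by full coalition enumeration
#'
#' Computes, for each player, the exact Shapley value of a characteristic
#' function \code{value(S)} evaluated over all subsets \code{S} of players.
#' \code{value} may return a vector (e.g. one value per record), in which
#' case Shapley values are computed elementwise and returned as a matrix.
#'
#' @param players character vector of player names (at most 12).
#' @param value function taking an integer vector of player indices
#'   (possibly empty) and returning a numeric scalar or fixed-length
#'   vector.
#' @return numeric matrix (rows = value elements, columns = players) of
#'   Shapley values; a 1-row matrix for scalar games.
#' @export
exact_shapley <- function(players, value) {
  n <- length(players)
  if (n > 12L) {
    stop("exact enumeration supports at most 12 players (got ", n,
         "); use a sampling approximation instead")
  }
  masks <- 0:(2^n - 1L)
  member <- function(mask, i) bitwAnd(mask, bitwShiftL(1L, i - 1L)) != 0L
  vals <- lapply(masks, function(m) value(which(vapply(
    seq_len(n), member, logical(1), mask = m))))
  m0 <- length(vals[[1]])
  stopifnot(all(lengths(vals) == m0))
  sizes <- vapply(masks, function(m) sum(vapply(
    seq_len(n), member, logical(1), mask = m)), integer(1))
  # weight of coalition S (not containing i): |S|! (n-|S|-1)! / n!
  wt <- exp(lfactorial(0:(n - 1)) + lfactorial(n - 1:n) - lfactorial(n))
  phi <- matrix(0, nrow = m0, ncol = n, dimnames = list(NULL, players))
  for (j in seq_along(masks)) {
    m <- masks[j]
    for (i in seq_len(n)) {
      if (member(m, i)) next
      with_i <- bitwOr(m, bitwShiftL(1L, i - 1L))
      phi[, i] <- phi[, i] + wt[sizes[j] + 1L] *
        (vals[[with_i + 1L]] - vals[[j]])
    }
  }
  phi
}

#' Exact Shapley feature attribution of foldability
#'
#' Attribution by retraining: the value of a feature coalition S is the
#' prediction of a classifier trained only on the features in S (the empty
#' coalition predicts the base foldability rate). Per-record Shapley values
#' over the grouped features (loop type I-III, loop length I-III, polarity)
#' are averaged to signed per-feature importances, and additionally
#' averaged within levels of each categorical feature to give signed
#' per-value attributions (e.g. how a \code{-p} loop at position I shifts
#' predicted foldability).
#'
#' @param records labelled records (see [label_foldable()]).
#' @param trainer function \code{(x, y, seed)} returning a prediction
#'   function \code{f(xnew)}; default a small gradient-boosted tree model.
#' @param seed RNG seed (each coalition model gets a seed derived from it).
#' @param nrounds boosting rounds for the default trainer.
#' @return list of class \code{g4_attribution}: \code{per_feature} (named
#'   signed means), \code{per_feature_abs} (mean absolute attributions,
#'   the usual importance ranking), \code{per_value} (data.frame
#'   feature/value/attribution/n), \code{per_record} (matrix),
#'   \code{base_value}, \code{full_value}.
#' @export
exact_shapley_attribution <- function(records, trainer = NULL,
                                      seed = 20250911, nrounds = 30) {
  stopifnot("foldable" %in% names(records))
  y <- records$foldable
  fm <- g4_feature_matrix(records)
  players <- names(fm$groups)
  if (is.null(trainer)) {
    trainer <- function(x, y, seed) {
      fit <- xgb_train_quiet(x, y, nrounds, seed)
      function(xnew) xgb_predict(fit, xnew)
    }
  }
  base <- mean(y)
  value <- function(idx) {
    if (length(idx) == 0L) return(rep(base, length(y)))
    cols <- unlist(fm$groups[idx], use.names = FALSE)
    x <- fm$x[, cols, drop = FALSE]
    pred <- trainer(x, y, seed + sum(2^(idx - 1)))
    as.numeric(pred(x))
  }
  phi <- exact_shapley(players, value)
  per_value <- list()
  tok <- t(vapply(records$topology, as_loop_tokens, character(3)))
  levels_of <- list(
    type_I = tok[, 1], type_II = tok[, 2], type_III = tok[, 3],
    len_I = as.character(records$len_I),
    len_II = as.character(records$len_II),
    len_III = as.character(records$len_III),
    polarity = records$polarity
  )
  for (nm in players) {
    v <- levels_of[[nm]]
    agg <- tapply(phi[, nm], v, mean)
    per_value[[nm]] <- data.frame(
      feature = nm, value = names(agg), attribution = as.numeric(agg),
      n = as.integer(table(v)[names(agg)]), stringsAsFactors = FALSE)
  }
  per_value <- do.call(rbind, per_value)
  rownames(per_value) <- NULL
  structure(
    list(per_feature = colMeans(phi),
         per_feature_abs = colMeans(abs(phi)),
         per_value = per_value,
         per_record = phi, base_value = base,
         full_value = value(seq_along(players))),
    class = "g4_attribution"
  )
}
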