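#' Majority-voting aggregation of component outcomes
#'
#' The baseline aggregator: each component casts its binary vote and the
#' subject is classified by the sign of the unweighted vote sum
#' `F = sum_m z_m`. `F > 0` classifies as AD (+1), `F < 0` as normal (-1);
#' the even-M tie `F = 0` resolves to +1, matching the tie rule used
#' everywhere else in the package.
#'
#' @param outcomes Outcome tibble with `z_<region_id>` columns (one row per
#'   subject), or a bare numeric/integer vector of votes for one subject.
#' @return For a tibble: the tibble with columns `vote_score` (`F`) and
#'   `vote_label` appended. For a vector: a one-row tibble with
#'   `vote_score` and `vote_label`.
#' @export
vote <- function(outcomes) {
  if (is.numeric(outcomes)) {
    if (length(outcomes) == 0L) abort("empty outcome vector")
    check_binary_pm1(as.integer(outcomes), "votes")
    f <- sum(outcomes)
    return(tibble::tibble(vote_score = as.integer(f),
                          vote_label = if (f >= 0) 1L else -1L))
  }
  z <- outcome_matrix(outcomes)
  f <- as.integer(rowSums(z))
  dplyr::mutate(outcomes, vote_score = f,
                vote_label = ifelse(f >= 0L, 1L, -1L))
}
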