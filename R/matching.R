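# Per-channel spectral similarity on the fixed 0-1000 scale, weighted-average
# fusion across the four cone-voltage channels, and the conjunctive hit rule:
# channel 1 (12 V) >= 850, each remaining channel >= 825, average >= 800.
#
# The commercial score behind the original workflow is proprietary. The open
# replacement is a cosine on square-root-transformed intensities over nominal
# m/z bins, scaled by 1000 and rounded half-up. Two bin supports are offered.
# The default, "reference", evaluates the cosine over the reference entry's
# own peaks: because this workflow has no chromatographic separation, a
# sample spectrum is the sum of everything that desorbs (co-formulated
# esters, oil matrix), and a usable match score must tolerate peaks the
# library fingerprint does not contain. A symmetric identity search over the
# union of both peak sets ("union") is also provided; it is the stricter,
# classical form, but for an additive k-component mixture it bounds every
# constituent's score at sqrt(1/k) of full scale (score 577 for k = 3),
# which would defeat the hit criteria for any cocktail sample.

round_half_up <- function(x) floor(x + 0.5)

#' Per-channel match score (0-1000)
#'
#' Cosine similarity between sqrt-intensity vectors, times 1000, rounded
#' half-up.
#'
#' With `mode = "reference"` (default) the vectors live on the reference
#' spectrum's nominal m/z bins and the query is interference-capped before
#' the cosine: the fingerprint is scaled to the query at the reference's
#' base bin (highest m/z on ties), and query intensity exceeding the scaled
#' fingerprint by more than `interference_factor` (default 3, far beyond
#' what multiplicative measurement noise produces) is attributed to
#' co-desorbing species and truncated to the fingerprint's proportion.
#' Acquisitions here have no chromatographic separation, so a sample
#' spectrum is the sum of every constituent plus matrix; without the cap, a
#' co-desorbing compound whose precursor falls on a minor fingerprint bin
#' (trenbolone's m/z 271 on the testosterone-ester ester-cleavage bin, for
#' instance) would corrupt the ratio and mask a genuinely present compound.
#' Moderate ratio mismatches — the signal that distinguishes, say, free
#' trenbolone's 271/253 pattern from the same two ions inside a trenbolone
#' ester's spectrum — stay untouched and count against the match, as do
#' deficits. If the base bin itself is absent from the query the compound
#' is taken as absent and the score is 0.
#'
#' With `mode = "union"` the vectors live on the union of both peak sets —
#' the classical symmetric identity search, appropriate for pure-standard
#' comparisons.
#'
#' Both modes give exactly 1000 for identical peak sets with proportional
#' intensities and 0 for disjoint peak sets, and both are invariant to
#' overall intensity scale (relative 0-100 vs library 0-999 compare
#' correctly).
#'
#' @param query,reference [ms_spectrum()] objects preprocessed with the same
#'   parameters (nominal bins, thresholded).
#' @param mode `"reference"` or `"union"`, see above.
#' @param intensity_power Exponent applied to intensities before the cosine,
#'   default 0.5 (square root).
#' @param interference_factor Excess factor beyond which query intensity on
#'   a fingerprint bin is truncated as interference (reference mode only);
#'   default 3, `Inf` disables the cap.
#' @return Integer score in \[0, 1000\].
#' @export
channel_score <- function(query, reference,
                          mode = c("reference", "union"),
                          intensity_power = 0.5,
                          interference_factor = 3) {
  mode <- match.arg(mode)
  if (nrow(query$peaks) == 0 || nrow(reference$peaks) == 0) {
    stop("cannot score an empty spectrum")
  }
  mz <- if (mode == "reference") sort(unique(reference$peaks$mz))
        else sort(unique(c(query$peaks$mz, reference$peaks$mz)))
  q <- numeric(length(mz)); r <- numeric(length(mz))
  qi <- match(query$peaks$mz, mz)
  q[qi[!is.na(qi)]] <- query$peaks$intensity[!is.na(qi)]
  r[match(reference$peaks$mz, mz)] <- reference$peaks$intensity
  if (mode == "reference" && is.finite(interference_factor)) {
    anchor <- which(r == max(r))
    anchor <- anchor[length(anchor)]  # ties: highest m/z (bins ascending)
    expected <- r * (q[anchor] / r[anchor])
    gross <- q > interference_factor * expected
    q[gross] <- expected[gross]
  }
  q <- q^intensity_power
  r <- r^intensity_power
  if (sum(q^2) == 0 || sum(r^2) == 0) return(0L)
  cosine <- sum(q * r) / (sqrt(sum(q^2)) * sqrt(sum(r^2)))
  as.integer(max(0, min(1000, round_half_up(1000 * cosine))))
}

#' Hit criteria
#'
#' The conjunctive decision rule for calling a library hit, with the three
#' thresholds the screening method fixes: score >= 850 in channel 1 (12 V),
#' >= 825 in each of the three remaining channels, and a weighted-average
#' score >= 800. All comparisons are inclusive. Weights for the average are
#' equal by default.
#'
#' @param channel1_min Channel-1 (lowest voltage) threshold, default 850.
#' @param other_channels_min Threshold for the remaining channels, default 825.
#' @param average_min Fused-average threshold, default 800.
#' @param weights Non-negative per-channel weights summing to 1, default
#'   equal over four channels.
#' @return A `match_criteria` list.
#' @export
match_criteria <- function(channel1_min = 850, other_channels_min = 825,
                           average_min = 800, weights = rep(0.25, 4)) {
  thr <- c(channel1_min, other_channels_min, average_min)
  if (any(thr < 0 | thr > 1000)) stop("thresholds must be in [0, 1000]")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1")
  }
  structure(
    list(channel1_min = channel1_min, other_channels_min = other_channels_min,
         average_min = average_min, weights = as.numeric(weights)),
    class = "match_criteria"
  )
}

#' Fuse per-channel scores into a weighted average
#'
#' Weighted arithmetic mean over the (already integer-rounded) channel
#' scores, in ascending-voltage order.
#'
#' @param channel_scores Numeric vector, one score per channel.
#' @param weights Non-negative weights summing to 1; default equal.
#' @return The weighted mean (double).
#' @export
fuse_scores <- function(channel_scores,
                        weights = rep(1 / length(channel_scores),
                                      length(channel_scores))) {
  if (length(channel_scores) != length(weights)) {
    stop("one weight per channel required")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1")
  }
  sum(channel_scores * weights)
}

#' Apply the hit criteria to one score vector
#'
#' @param channel_scores Named or ascending-voltage-ordered scores; the
#'   first element is channel 1 (lowest cone voltage).
#' @param average_score The fused average; computed from `channel_scores`
#'   and the criteria weights when omitted.
#' @param criteria A [match_criteria()].
#' @return Logical: hit or not. Boundary values pass (inclusive thresholds).
#' @export
apply_criteria <- function(channel_scores, average_score = NULL,
                           criteria = match_criteria()) {
  if (is.null(average_score)) {
    average_score <- fuse_scores(channel_scores, criteria$weights)
  }
  channel_scores[1] >= criteria$channel1_min &&
    all(channel_scores[-1] >= criteria$other_channels_min) &&
    average_score >= criteria$average_min
}

#' Screen a four-channel query against a library
#'
#' Scores the query against every library entry channel-by-channel, fuses
#' the scores, applies the hit criteria, and returns the report sorted by
#' average score (descending; ties broken by abbreviation, lexicographic).
#' The query is preprocessed with the library's own build parameters, so
#' query and references always see the identical chain (the preprocessing
#' is idempotent, so an already-preprocessed query is unchanged).
#'
#' @param query An [ms_multichannel()] acquisition.
#' @param library An `ms_library` from [build_library()] or
#'   [library_from_msp()].
#' @param criteria A [match_criteria()].
#' @param mode Score support passed to [channel_score()].
#' @return A `screening_report` data frame: `compound`, one `score_<V>v`
#'   column per channel, `average_score`, `hit`.
#' @export
screen <- function(query, library, criteria = match_criteria(),
                   mode = c("reference", "union")) {
  mode <- match.arg(mode)
  if (length(library$entries) == 0) stop("empty library")
  query <- preprocess_multichannel(ms_multichannel(query),
                                   library$build_params)
  voltages <- names(library$entries[[1]]$channels)
  rows <- lapply(names(library$entries), function(abbr) {
    entry <- library$entries[[abbr]]
    scores <- vapply(voltages, function(v) {
      channel_score(query[[v]], entry$channels[[v]], mode = mode)
    }, integer(1))
    avg <- fuse_scores(scores, criteria$weights)
    out <- as.list(scores)
    names(out) <- paste0("score_", voltages, "v")
    c(list(compound = abbr), out,
      list(average_score = avg,
           hit = apply_criteria(scores, avg, criteria)))
  })
  rep <- do.call(rbind, lapply(rows, as.data.frame))
  rep <- rep[order(-rep$average_score, rep$compound), , drop = FALSE]
  rownames(rep) <- NULL
  class(rep) <- c("screening_report", "data.frame")
  rep
}

#' @export
print.screening_report <- function(x, n = Inf, ...) {
  cat(sprintf("Screening report: %d compounds, %d hit(s)%s\n",
              nrow(x), sum(x$hit),
              if ("sir_confirmed" %in% names(x))
                sprintf(", %d SIR-confirmed", sum(x$sir_confirmed)) else ""))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 5, ...)
  invisible(x)
}
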