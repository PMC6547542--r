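#' Generate peak sequences with planted motif instances
#'
#' Draws a random background sequence for every peak (resampled until it
#' contains no exact consensus occurrence of any supplied motif on either
#' strand), then plants non-overlapping consensus instances: the number per
#' peak is Poisson with mean `motifRatePromoter` for promoter-located peaks
#' and `motifRateDistal` for distal peaks (truncated to what fits), so
#' promoter peaks carry the high-multiplicity distribution and distal peaks
#' the sparse one.  Instances are placed on a random strand (the reverse
#' complement of the consensus is planted for `-`) and recorded.
#'
#' @param peaks the truth-annotated landscape from [generatePeakLandscape()]
#'   (needs the `location` metadata column).
#' @param config a [SimulationConfig()].
#' @param pwms motif models whose consensus strings are planted; the bundled
#'   [spLikePWM()] by default.
#' @return `list(sequences = <named DNAStringSet>, placements =
#'   <data.frame peak, motif, offset, strand>)`; offsets are 0-based on the
#'   forward strand.
#' @export
generateSequencesWithMotifs <- function(peaks, config, pwms = spLikePWM()) {
  stopifnot(is(config, "SimulationConfig"))
  .checkPeakSet(peaks)
  if (is(pwms, "PositionWeightMatrix")) pwms <- list(pwms)
  loc <- mcols(peaks)$location
  if (is.null(loc))
    stop("peaks must carry a 'location' truth column")
  consensi <- vapply(pwms, pwmConsensus, "")
  motifNames <- vapply(pwms, function(p) p@name, "")
  widths <- width(peaks)
  if (any(nchar(consensi) >= min(widths)))
    stop("motif length must be smaller than the peak width")
  .withSeed(.childSeed(config@seed, "sequences"), {
    seqs <- character(length(peaks))
    placements <- list()
    for (i in seq_along(peaks)) {
      w <- widths[i]
      repeat {
        s <- sample(.BASES, w, replace = TRUE)
        str <- paste(s, collapse = "")
        clean <- TRUE
        for (cons in consensi) {
          rc <- paste(rev(.COMP[strsplit(cons, "")[[1L]]]), collapse = "")
          if (grepl(cons, str, fixed = TRUE) ||
              grepl(rc, str, fixed = TRUE)) { clean <- FALSE; break }
        }
        if (clean) break
      }
      rate <- if (loc[i] == "promoter") config@motifRatePromoter
              else config@motifRateDistal
      occupied <- matrix(numeric(0), ncol = 2)
      for (m in seq_along(pwms)) {
        L <- nchar(consensi[m])
        k <- min(rpois(1L, rate), w %/% L)
        placed <- 0L
        tries <- 0L
        while (placed < k && tries < 200L) {
          tries <- tries + 1L
          off <- sample.int(w - L + 1L, 1L) - 1L  # 0-based
          if (nrow(occupied) &&
              any(off < occupied[, 2] & off + L - 1L >= occupied[, 1]))
            next
          strand <- sample(c("+", "-"), 1L)
          inst <- if (strand == "+") consensi[m]
                  else paste(rev(.COMP[strsplit(consensi[m], "")[[1L]]]),
                             collapse = "")
          s[(off + 1L):(off + L)] <- strsplit(inst, "")[[1L]]
          occupied <- rbind(occupied, c(off, off + L))
          placements[[length(placements) + 1L]] <- data.frame(
            peak = names(peaks)[i], motif = motifNames[m],
            offset = off, strand = strand)
          placed <- placed + 1L
        }
      }
      seqs[i] <- paste(s, collapse = "")
    }
    placements <- if (length(placements)) do.call(rbind, placements)
                  else data.frame(peak = character(), motif = character(),
                                  offset = integer(), strand = character())
    dss <- DNAStringSet(seqs)
    names(dss) <- names(peaks)
    list(sequences = dss, placements = placements)
  })
}
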