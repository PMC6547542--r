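# PWM scanning and motif-content summaries.

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' @describeIn PositionWeightMatrix the consensus string (highest-probability
#'   base at every position).
#' @param pwm a `PositionWeightMatrix`.
#' @export
pwmConsensus <- function(pwm) {
  stopifnot(is(pwm, "PositionWeightMatrix"))
  paste(.BASES[apply(pwm@probs, 1, which.max)], collapse = "")
}

#' @describeIn PositionWeightMatrix maximum achievable log2-odds score.
#' @export
pwmMaxScore <- function(pwm) {
  stopifnot(is(pwm, "PositionWeightMatrix"))
  lo <- log2(pwm@probs) - rep(log2(pwm@background), each = nrow(pwm@probs))
  sum(apply(lo, 1, max))
}

#' A bundled synthetic Sp-like GC-box PWM
#'
#' A sharp 9-bp matrix with consensus `GGGGCGGGG` (probability `peak` on
#' the consensus base, the remainder spread evenly), standing in for the
#' Sp-family GC-box motif in tests and examples.  It is a synthetic matrix,
#' not a database entry.
#'
#' @param peak probability of the consensus base at each position.
#' @return a [`PositionWeightMatrix-class`].
#' @export
spLikePWM <- function(peak = 0.97) {
  cons <- c("G", "G", "G", "G", "C", "G", "G", "G", "G")
  probs <- matrix((1 - peak) / 3, nrow = length(cons), ncol = 4,
                  dimnames = list(NULL, .BASES))
  probs[cbind(seq_along(cons), match(cons, .BASES))] <- peak
  PositionWeightMatrix("SpLike_GCbox", probs)
}

#' Read position weight matrices
#'
#' Reads either the package's minimal tabular format (a `>name` header line
#' followed by L whitespace-separated rows of 4 base probabilities in
#' A, C, G, T order; several motifs may follow each other) or JASPAR-style
#' count matrices (`>id name` followed by four `A [ ... ]` rows), whose
#' counts are converted to probabilities with a pseudocount.
#'
#' @param path file path.
#' @param pseudocount added to every count before conversion (JASPAR input
#'   only).
#' @return a named list of [`PositionWeightMatrix-class`] objects.
#' @seealso [writePWM()]
#' @export
readPWM <- function(path, pseudocount = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no '>' motif header found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- list()
  for (i in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[i]])
    name <- strsplit(header, "\\s+")[[1L]]
    name <- name[length(name)]
    body <- lines[seq(starts[i] + 1L, ends[i])]
    if (any(grepl("^[ACGT]\\s*\\[", body))) {
      rows <- lapply(.BASES, function(b) {
        ln <- body[grepl(paste0("^", b, "\\s*\\["), body)]
        if (length(ln) != 1L)
          stop("motif '", name, "': missing or duplicated ", b, " row")
        as.numeric(strsplit(trimws(gsub("^[ACGT]\\s*\\[|\\]", "", ln)),
                            "\\s+")[[1L]])
      })
      counts <- do.call(cbind, rows) + pseudocount
      probs <- counts / rowSums(counts)
    } else {
      probs <- do.call(rbind, lapply(seq_along(body), function(j) {
        v <- as.numeric(strsplit(body[j], "\\s+")[[1L]])
        if (length(v) != 4L || anyNA(v))
          stop("motif '", name, "', row ", j,
               ": expected 4 numeric probabilities")
        v
      }))
      probs <- probs / rowSums(probs)
    }
    out[[name]] <- PositionWeightMatrix(name, probs)
  }
  out
}

#' Write position weight matrices in the tabular format
#'
#' @param pwms a `PositionWeightMatrix` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePWM <- function(pwms, path) {
  if (is(pwms, "PositionWeightMatrix")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (pwm in pwms) {
    writeLines(paste0(">", pwm@name), con)
    write.table(format(pwm@probs, digits = 10), con, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# Integer-encode a sequence; N (or any other letter) becomes NA.
.encodeSeq <- function(sequence) {
  if (is(sequence, "DNAString") || is(sequence, "DNAStringSet"))
    sequence <- as.character(sequence)
  match(strsplit(toupper(sequence), "")[[1L]], .BASES)
}

.logOdds <- function(pwm) {
  log2(pwm@probs) - rep(log2(pwm@background), each = nrow(pwm@probs))
}

.threshold <- function(pwm) {
  if (!is.na(pwm@scoreThreshold)) pwm@scoreThreshold
  else 0.8 * pwmMaxScore(pwm)
}

#' Scan a sequence with a PWM
#'
#' Slides the motif over both strands and reports every window whose
#' log2-odds score against the background model reaches the threshold
#' (`scoreThreshold` of the matrix, or 80% of its maximum achievable score
#' when unset).  Windows containing `N` are skipped.  Offsets are 0-based on
#' the forward strand for both strands.
#'
#' @param sequence a character string or `DNAString` over A, C, G, T, N.
#' @param pwm a [`PositionWeightMatrix-class`].
#' @return a data.frame with columns `offset`, `strand`, `score`, ordered by
#'   offset then strand; zero rows when the sequence is shorter than the
#'   motif.
#' @export
scanPWM <- function(sequence, pwm) {
  stopifnot(is(pwm, "PositionWeightMatrix"))
  code <- .encodeSeq(sequence)
  L <- nrow(pwm@probs)
  n <- length(code)
  empty <- data.frame(offset = integer(), strand = character(),
                      score = numeric())
  if (n < L) return(empty)
  lo <- .logOdds(pwm)
  # minus-strand hits on the forward coordinates: score with the
  # reverse-complemented matrix
  loRC <- lo[rev(seq_len(L)), c(4L, 3L, 2L, 1L), drop = FALSE]
  nw <- n - L + 1L
  fwd <- numeric(nw); rev <- numeric(nw)
  for (j in seq_len(L)) {
    b <- code[j:(j + nw - 1L)]
    fwd <- fwd + lo[j, b]
    rev <- rev + loRC[j, b]
  }
  thr <- .threshold(pwm)
  hitF <- which(!is.na(fwd) & fwd >= thr)
  hitR <- which(!is.na(rev) & rev >= thr)
  out <- data.frame(
    offset = c(hitF, hitR) - 1L,
    strand = rep(c("+", "-"), c(length(hitF), length(hitR))),
    score = c(fwd[hitF], rev[hitR]))
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Count non-overlapping motif hits per peak
#'
#' Scans every peak sequence with every PWM and counts non-overlapping hits
#' by greedy left-to-right selection among threshold-passing windows (at a
#' tie in offset the forward strand is taken first); this deterministic rule
#' resolves overlapping candidate windows.
#'
#' @param sequences named character vector or `DNAStringSet` of peak
#'   sequences.
#' @param pwms a `PositionWeightMatrix` or list of them.
#' @return an integer matrix, peaks x motifs, with the scan threshold
#'   recorded in `attr(x, "thresholds")`.
#' @export
countMotifsPerPeak <- function(sequences, pwms) {
  if (is(pwms, "PositionWeightMatrix")) pwms <- list(pwms)
  names(pwms) <- vapply(pwms, function(p) p@name, "")
  if (is(sequences, "DNAStringSet")) {
    seqs <- as.character(sequences)
  } else seqs <- sequences
  if (length(seqs) && (is.null(names(seqs)) || anyDuplicated(names(seqs))))
    stop("sequences must carry unique peak ids as names")
  out <- matrix(0L, nrow = length(seqs), ncol = length(pwms),
                dimnames = list(names(seqs), names(pwms)))
  for (m in seq_along(pwms)) {
    L <- nrow(pwms[[m]]@probs)
    for (i in seq_along(seqs)) {
      hits <- scanPWM(seqs[[i]], pwms[[m]])
      k <- 0L; lastEnd <- -1L
      for (h in seq_len(nrow(hits))) {
        if (hits$offset[h] > lastEnd) {
          k <- k + 1L
          lastEnd <- hits$offset[h] + L - 1L
        }
      }
      out[i, m] <- k
    }
  }
  attr(out, "thresholds") <- vapply(pwms, .threshold, 0)
  out
}

#' Motif-count distributions by peak class and location
#'
#' For every peak class, every location stratum (`all`, `promoter`,
#' `distal`) and every motif, tabulates how many peaks carry 0, 1, 2, ...
#' hits, with counts of `cap` or more pooled into the top bin — the binned
#' bar-chart summary of motif multiplicity.
#'
#' @param counts peaks x motifs matrix from [countMotifsPerPeak()].
#' @param classes named character vector of class labels covering all peaks
#'   in `counts` (e.g. the `label` column of [classifySharedSpecific()]).
#' @param locations named character vector `promoter`/`distal` covering all
#'   peaks (from [annotateLocation()]).
#' @param cap top histogram bin (`>= cap` hits are pooled).
#' @return a data.frame with columns `class`, `stratum`, `motif`, `bin`
#'   (`"0" ... ">=cap"`) and `n`; within each (class, stratum, motif) the
#'   bins sum to the number of peaks in the stratum.
#' @export
motifCountDistribution <- function(counts, classes, locations, cap = 9L) {
  ids <- rownames(counts)
  if (!all(ids %in% names(classes)) || !all(ids %in% names(locations)))
    stop("classes and locations must cover every peak in 'counts'")
  binLabels <- c(as.character(0:(cap - 1L)), paste0(">=", cap))
  res <- list()
  for (cl in sort(unique(classes[ids]))) {
    inClass <- ids[classes[ids] == cl]
    strata <- list(all = inClass,
                   promoter = inClass[locations[inClass] == "promoter"],
                   distal = inClass[locations[inClass] == "distal"])
    for (st in names(strata)) {
      for (m in colnames(counts)) {
        v <- pmin(counts[strata[[st]], m], cap)
        tab <- tabulate(v + 1L, nbins = cap + 1L)
        res[[length(res) + 1L]] <- data.frame(
          class = cl, stratum = st, motif = m, bin = binLabels, n = tab)
      }
    }
  }
  do.call(rbind, res)
}

#' Motif enrichment between two peak sets
#'
#' For every motif, builds the 2x2 table of peaks with at least one hit
#' versus none in the foreground and background sets, and reports the odds
#' ratio (with the Haldane 0.5 correction when any cell is zero), the
#' two-sided Fisher exact p value and the Benjamini-Hochberg q value across
#' motifs.
#'
#' @param counts peaks x motifs matrix from [countMotifsPerPeak()].
#' @param foregroundIds,backgroundIds disjoint, non-empty peak id sets.
#' @return a data.frame with one row per motif: `motif`, `fgWith`,
#'   `fgWithout`, `bgWith`, `bgWithout`, `oddsRatio`, `p`, `q`.
#' @export
motifEnrichment <- function(counts, foregroundIds, backgroundIds) {
  if (!length(foregroundIds) || !length(backgroundIds))
    stop("foreground and background must both be non-empty")
  if (length(intersect(foregroundIds, backgroundIds)))
    stop("foreground and background must be disjoint")
  missing <- setdiff(c(foregroundIds, backgroundIds), rownames(counts))
  if (length(missing))
    stop("peak id(s) missing from counts: ",
         paste(head(missing, 3), collapse = ", "))
  rows <- lapply(colnames(counts), function(m) {
    a <- sum(counts[foregroundIds, m] >= 1L)  # fg with hit
    b <- length(foregroundIds) - a
    c_ <- sum(counts[backgroundIds, m] >= 1L)
    d <- length(backgroundIds) - c_
    tab <- matrix(c(a, b, c_, d), 2)
    or <- if (any(tab == 0))
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    else (a * d) / (b * c_)
    p <- fisher.test(tab)$p.value
    data.frame(motif = m, fgWith = a, fgWithout = b, bgWith = c_,
               bgWithout = d, oddsRatio = or, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out
}
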