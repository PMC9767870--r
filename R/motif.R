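#' Build a position weight matrix from a consensus sequence
#'
#' Each column assigns probability `1 - 3 * pseudocount` to the consensus
#' base and `pseudocount` to the others.
#'
#' @param consensus Consensus string over ACGT (default the AP1
#'   TPA-response element TGACTCA).
#' @param pseudocount Off-consensus probability per base (default 0.01).
#' @param name Motif name.
#' @param background Background base frequencies (default uniform).
#' @return List of class `pwm`: `name`, `prob` (4 x width matrix, rows
#'   A/C/G/T), `background`.
#' @export
pwm_from_consensus <- function(consensus = "TGACTCA", pseudocount = 0.01,
                               name = "AP1", background = rep(0.25, 4)) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(toupper(consensus), "")[[1]]
  if (!all(chars %in% bases)) stop_fmt("consensus must be over ACGT")
  prob <- matrix(pseudocount, 4, length(chars),
                 dimnames = list(bases, NULL))
  for (j in seq_along(chars)) prob[chars[j], j] <- 1 - 3 * pseudocount
  new_pwm(name, prob, background)
}

new_pwm <- function(name, prob, background = rep(0.25, 4)) {
  if (any(abs(colSums(prob) - 1) > 1e-6))
    stop_fmt("PWM columns must sum to 1")
  if (any(prob <= 0)) stop_fmt("PWM probabilities must be positive")
  names(background) <- rownames(prob) <- c("A", "C", "G", "T")
  structure(list(name = name, prob = prob, background = background),
            class = "pwm")
}

#' Read a JASPAR-style PWM text file
#'
#' Parses the `>NAME` header followed by four `A [ n n ... ]` count rows;
#' counts are converted to probabilities with a pseudocount.
#'
#' @param path File path.
#' @param pseudocount Added to every count before normalization.
#' @return A `pwm`.
#' @export
read_jaspar <- function(path, pseudocount = 0.5) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  name <- sub("^>\\s*", "", lines[grepl("^>", lines)][1])
  rows <- lines[!grepl("^>", lines)][1:4]
  parsed <- lapply(rows, function(l) {
    body <- sub("^\\s*[ACGT]", "", l)
    as.numeric(regmatches(body, gregexpr("[0-9.]+", body))[[1]])
  })
  widths <- lengths(parsed)
  if (length(unique(widths)) != 1)
    stop_fmt("JASPAR rows have unequal widths")
  counts <- do.call(rbind, parsed) + pseudocount
  prob <- sweep(counts, 2, colSums(counts), "/")
  rownames(prob) <- c("A", "C", "G", "T")
  new_pwm(name %||% "motif", prob)
}

#' Maximum attainable log-odds score of a PWM
#' @param pwm A `pwm`.
#' @return The sum over positions of the best per-base log2 odds.
#' @export
pwm_max_score <- function(pwm) {
  lo <- log2(pwm$prob / pwm$background)
  sum(apply(lo, 2, max))
}

#' Scan a sequence for PWM hits on both strands
#'
#' Scores every offset with the log2 odds
#' `log2(P(window | pwm) / P(window | background))` on the forward and
#' reverse strands. Windows containing N are skipped. Reverse-strand hits
#' are reported at their forward-strand 5' coordinate with a strand flag.
#' Coordinates are 0-based.
#'
#' @param sequence Character string over ACGTN.
#' @param pwm A `pwm`.
#' @param score_min Minimum reported score.
#' @return data.frame with `start` (0-based forward coordinate), `strand`,
#'   `score`; empty if the sequence is shorter than the motif.
#' @export
scan_pwm <- function(sequence, pwm, score_min) {
  w <- ncol(pwm$prob)
  lo <- log2(pwm$prob / pwm$background)
  empty <- data.frame(start = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  scan_strand <- function(seqchars) {
    L <- length(seqchars)
    if (L < w) return(NULL)
    code <- match(seqchars, c("A", "C", "G", "T"))
    n_off <- L - w + 1
    sc <- numeric(n_off)
    ok <- rep(TRUE, n_off)
    for (j in seq_len(w)) {
      cj <- code[j:(j + n_off - 1)]
      bad <- is.na(cj)
      ok <- ok & !bad
      cj[bad] <- 1L
      sc <- sc + lo[cbind(cj, j)]
    }
    list(score = sc, ok = ok)
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  if (L < w) return(empty)
  fwd <- scan_strand(chars)
  rcmap <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev_chars <- rev(unname(rcmap[chars]))
  rev_scan <- scan_strand(rev_chars)
  hits_f <- which(fwd$ok & fwd$score >= score_min)
  hits_r <- which(rev_scan$ok & rev_scan$score >= score_min)
  out <- rbind(
    if (length(hits_f))
      data.frame(start = hits_f - 1L, strand = "+",
                 score = fwd$score[hits_f], stringsAsFactors = FALSE),
    if (length(hits_r))
      # rc offset o (0-based) covers forward positions (L - o - w)..(L - o - 1)
      data.frame(start = L - (hits_r - 1L) - w, strand = "-",
                 score = rev_scan$score[hits_r], stringsAsFactors = FALSE))
  if (is.null(out)) return(empty)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan many peak sequences for a motif
#'
#' @param seqs Named character vector of sequences.
#' @param pwm A `pwm`.
#' @param score_min Minimum score; defaults to 95% of the maximum
#'   attainable score (effectively consensus-level matches for sharp PWMs).
#' @return Named logical vector: does each peak contain a hit?
#' @export
scan_peaks <- function(seqs, pwm, score_min = 0.95 * pwm_max_score(pwm)) {
  vapply(seqs, function(s) nrow(scan_pwm(s, pwm, score_min)) > 0,
         logical(1))
}
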