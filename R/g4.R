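# Canonical G-quadruplex motif scanning: four runs of >= 3 G separated by
# loops of 1-7 bases (G3+ N1-7 G3+ N1-7 G3+ N1-7 G3+).

# consecutive run length of `flag` starting at each position
.runLenFrom <- function(flag) {
  r <- rle(flag)
  rem <- sequence(r$lengths, from = r$lengths, by = -1L)
  rem[!flag] <- 0L
  rem
}

# One-strand scan on a character vector; returns matrix of (start, end).
# Matches are extracted left to right, shortest-first at each start, with
# non-overlapping consumption of matched spans. G runs longer than maxRun
# are still matched (the first stem absorbs leading Gs; internal stems are
# capped at maxRun for tractability of the exhaustive oracle).
.scanG4Strand <- function(chars, maxRun = 10L, loopMax = 7L) {
  n <- length(chars)
  rem <- .runLenFrom(chars == "G")
  cumBad <- c(0L, cumsum(!(chars %in% c("A", "C", "G", "T"))))
  memo <- new.env(hash = TRUE, parent = emptyenv())
  best <- function(pos, stems) {
    key <- sprintf("%d.%d", pos, stems)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    res <- Inf
    if (pos <= n - 2L && rem[pos] >= 3L) {
      if (stems == 1L) {
        res <- pos + 2L
      } else {
        for (g in 3:min(rem[pos], maxRun)) {
          for (l in 1:loopMax) {
            np <- pos + g + l
            if (np + 2L > n) break
            if (rem[np] >= 3L && cumBad[np] - cumBad[pos + g] == 0L) {
              cand <- best(np, stems - 1L)
              if (cand < res) res <- cand
            }
          }
        }
      }
    }
    memo[[key]] <- res
    res
  }
  starts <- which(rem >= 3L)
  spans <- vector("list", 0)
  cur <- 1L
  for (s in starts) {
    if (s < cur) next
    e <- best(s, 4L)
    if (is.finite(e)) {
      spans[[length(spans) + 1L]] <- c(s, as.integer(e))
      cur <- as.integer(e) + 1L
    }
  }
  if (!length(spans)) matrix(integer(0), 0, 2)
  else do.call(rbind, spans)
}

#' Scan a sequence for canonical G4 motifs
#'
#' Finds instances of the canonical G-quadruplex motif: four runs of at least
#' three guanines separated by loops of one to seven bases. Matches are
#' reported left to right, shortest first, consuming matched spans so
#' reported motifs on one strand never overlap. Motifs on the opposite strand
#' are found by scanning the reverse complement. Loops never span ambiguous
#' (non-ACGT) bases.
#'
#' @param x Sequence: a character string, `DNAString`, or one element of a
#'   `DNAStringSet`.
#' @param bothStrands Also scan the reverse complement (default TRUE).
#' @param maxRun Cap on internal G-run length explored per stem (default 10);
#'   longer runs are still matched through the preceding stem.
#' @return `data.frame` with 1-based inclusive `start`, `end` and `strand`,
#'   sorted by position.
#' @examples
#' scanG4("GGGTGGGTGGGTGGG")   # one motif spanning the whole string
#' scanG4("GGGTGGGTGGG")       # three runs only: no motif
#' @export
scanG4 <- function(x, bothStrands = TRUE, maxRun = 10L) {
  s <- toupper(as.character(x))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  fwd <- .scanG4Strand(chars, maxRun = maxRun)
  out <- if (nrow(fwd))
    data.frame(start = fwd[, 1], end = fwd[, 2], strand = "+")
  else data.frame(start = integer(0), end = integer(0),
                  strand = character(0))
  if (bothStrands && n) {
    rcChars <- strsplit(as.character(reverseComplement(DNAString(s))),
                        "", fixed = TRUE)[[1]]
    rev <- .scanG4Strand(rcChars, maxRun = maxRun)
    if (nrow(rev))
      out <- rbind(out, data.frame(start = n - rev[, 2] + 1L,
                                   end = n - rev[, 1] + 1L, strand = "-"))
  }
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tile the genome into G4 windows
#'
#' Non-overlapping fixed-width windows per chromosome; windows containing
#' ambiguous bases are removed, the remaining windows are flagged when any
#' canonical G4 motif overlaps them by at least one base pair.
#'
#' @param genome `DNAStringSet`.
#' @param window Window width in bp (default 100).
#' @param bothStrands Passed to [scanG4()].
#' @return `GRanges` of windows with metadata columns `has_motif` and
#'   `n_motifs`; the motif spans themselves are attached as
#'   `metadata(.)$motifs` (a `GRanges` with strand).
#' @export
g4WindowSet <- function(genome, window = 100, bothStrands = TRUE) {
  allWin <- list(); allMot <- list()
  for (chr in names(genome)) {
    len <- length(genome[[chr]])
    k <- floor(len / window)
    if (k == 0) next
    win <- GRanges(chr, IRanges(start = seq_len(k) * window - window + 1,
                                width = window))
    lf <- letterFrequency(Views(genome[[chr]],
                                IRanges(start(win), end(win))),
                          c("A", "C", "G", "T"))
    win <- win[rowSums(lf) == window]  # drop windows with ambiguous bases
    spans <- scanG4(genome[[chr]], bothStrands = bothStrands)
    mot <- if (nrow(spans))
      GRanges(chr, IRanges(spans$start, spans$end), strand = spans$strand)
    else GRanges()
    mcols(win)$n_motifs <- countOverlaps(win, mot, minoverlap = 1L,
                                         ignore.strand = TRUE)
    mcols(win)$has_motif <- mcols(win)$n_motifs > 0L
    allWin[[chr]] <- win
    allMot[[chr]] <- mot
  }
  win <- suppressWarnings(do.call(c, unname(allWin)))
  seqlengths(win) <- vapply(names(genome), function(ch)
    length(genome[[ch]]), numeric(1))[seqlevels(win)]
  names(win) <- regionIds(win)
  metadata(win)$motifs <- suppressWarnings(do.call(c, unname(allMot)))
  win
}

#' Fraction of enriched regions containing a G4 motif
#'
#' @param ebs `GRanges` of OG-enriched regions (one genotype), or a named
#'   list of such.
#' @param g4windows Output of [g4WindowSet()]; only windows with
#'   `has_motif == TRUE` count as G4 regions.
#' @return Fraction of regions overlapping at least one retained G4 window
#'   (per genotype when a list is given); `NA` with a message for an empty
#'   region set.
#' @export
ebG4Overlap <- function(ebs, g4windows) {
  retained <- g4windows[mcols(g4windows)$has_motif]
  one <- function(gr) {
    if (!length(gr)) {
      message("empty enriched-region set: overlap fraction undefined")
      return(NA_real_)
    }
    mean(overlapsAny(gr, retained, minoverlap = 1L, ignore.strand = TRUE))
  }
  if (is(ebs, "GRanges")) one(ebs)
  else vapply(ebs, one, numeric(1))
}
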