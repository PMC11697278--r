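# Independent brute-force G4 oracle: enumerates every (run, loop)
# decomposition of the canonical motif (four G runs >= 3, loops 1-7, G runs
# capped at maxRun) by direct character checks, then applies the same
# selection rule as the scanner (leftmost start, shortest end, non-overlap).

g4OracleStrand <- function(s, maxRun = 10) {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  n <- length(chars)
  gAt <- function(p) p <= n && chars[p] == "G"
  okLoop <- function(a, b) all(chars[a:b] %in% c("A", "C", "G", "T"))
  # all end positions of a motif starting exactly at pos with `stems` stems
  allEnds <- function(pos, stems) {
    if (!(gAt(pos) && gAt(pos + 1) && gAt(pos + 2))) return(integer(0))
    res <- integer(0)
    g <- 3
    while (g <= maxRun && pos + g - 1 <= n &&
             all(chars[pos:(pos + g - 1)] == "G")) {
      if (stems == 1) {
        res <- c(res, pos + g - 1)
      } else {
        for (l in 1:7) {
          nxt <- pos + g + l
          if (nxt + 2 > n) break
          if (okLoop(pos + g, nxt - 1))
            res <- c(res, allEnds(nxt, stems - 1))
        }
      }
      g <- g + 1
    }
    unique(res)
  }
  spans <- NULL
  cur <- 1
  pos <- 1
  while (pos <= n - 14) {
    if (pos >= cur) {
      ends <- allEnds(pos, 4)
      if (length(ends)) {
        e <- min(ends)
        spans <- rbind(spans, c(pos, e))
        cur <- e + 1
        pos <- e
      }
    }
    pos <- pos + 1
  }
  if (is.null(spans)) matrix(integer(0), 0, 2) else spans
}

g4Oracle <- function(s, maxRun = 10) {
  n <- nchar(s)
  fwd <- g4OracleStrand(s, maxRun)
  out <- if (nrow(fwd))
    data.frame(start = fwd[, 1], end = fwd[, 2], strand = "+")
  else data.frame(start = integer(0), end = integer(0),
                  strand = character(0))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  rev <- g4OracleStrand(rc, maxRun)
  if (nrow(rev))
    out <- rbind(out, data.frame(start = n - rev[, 2] + 1,
                                 end = n - rev[, 1] + 1, strand = "-"))
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

randomSeq <- function(len, probG = 0.25) {
  p <- c(probG, (1 - probG) / 3, (1 - probG) / 3, (1 - probG) / 3)
  paste(sample(c("G", "C", "A", "T"), len, replace = TRUE, prob = p),
        collapse = "")
}
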