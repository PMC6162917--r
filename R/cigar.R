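#' Summarize CIGAR strings
#'
#' Per-record operation totals for CIGARs over M/I/D/S/H (N/=/X accepted;
#' = and X count as aligned, N as a reference skip).
#'
#' @param cigars Character vector of CIGAR strings (NA allowed).
#' @return Data frame with `aligned` (M bases, query-consuming and aligned),
#'   `ins`, `del`, `soft_clip`, `hard_clip`, `left_clip`, `right_clip`
#'   (soft+hard at each end), `ref_width` (M+D+N), `query_length` (M+I+S).
#' @export
cigar_summary <- function(cigars) {
  n <- length(cigars)
  out <- data.frame(aligned = rep(NA_integer_, n), ins = NA_integer_,
                    del = NA_integer_, soft_clip = NA_integer_,
                    hard_clip = NA_integer_, left_clip = NA_integer_,
                    right_clip = NA_integer_, ref_width = NA_integer_,
                    query_length = NA_integer_)
  ok <- which(!is.na(cigars) & cigars != "*")
  if (length(ok) == 0) return(out)
  toks <- regmatches(cigars[ok], gregexpr("\\d+[MIDNSHP=X]", cigars[ok]))
  ntok <- lengths(toks)
  grp <- rep(seq_along(ok), ntok)
  tk <- unlist(toks, use.names = FALSE)
  len <- as.integer(sub(".$", "", tk))
  op <- substr(tk, nchar(tk), nchar(tk))
  op[op %in% c("=", "X")] <- "M"
  tot <- function(sel) {
    v <- numeric(length(ok))
    if (any(sel)) {
      r <- rowsum(len[sel], grp[sel])
      v[as.integer(rownames(r))] <- r[, 1]
    }
    as.integer(v)
  }
  aligned <- tot(op == "M")
  ins <- tot(op == "I")
  del <- tot(op == "D")
  skip <- tot(op == "N")
  sc <- tot(op == "S")
  hc <- tot(op == "H")
  # leading/trailing clip runs: token positions before the first / after the
  # last non-clip operation of each record
  pos_in_rec <- sequence(ntok)
  is_clip <- op %in% c("S", "H")
  big <- max(ntok) + 1L
  first_nonclip <- vapply(split(ifelse(is_clip, big, pos_in_rec), grp),
                          min, 0)
  last_nonclip <- vapply(split(ifelse(is_clip, 0L, pos_in_rec), grp), max, 0)
  lclip <- tot(is_clip & pos_in_rec < first_nonclip[grp])
  rclip <- tot(is_clip & pos_in_rec > last_nonclip[grp])
  out$aligned[ok] <- aligned
  out$ins[ok] <- ins
  out$del[ok] <- del
  out$soft_clip[ok] <- sc
  out$hard_clip[ok] <- hc
  out$left_clip[ok] <- lclip
  out$right_clip[ok] <- rclip
  out$ref_width[ok] <- aligned + del + skip
  out$query_length[ok] <- aligned + ins + sc
  out
}
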