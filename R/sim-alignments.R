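#' Emit truth-consistent alignment records for simulated reads
#'
#' Stands in for a read mapper: each read is aligned to the contig of the
#' reference tiling (`contig_map`) that contains the majority of its origin
#' interval, with any overhang past the contig boundary soft-clipped. For
#' inversion-chimera reads only the longer arm is aligned and the other arm
#' is soft-clipped. Reads whose source genome is absent from the tiling
#' (e.g. contaminant-derived reads against the metagenome) or whose aligned
#' arm overlaps no contig (e.g. an inverted arm landing in an amplification
#' dropout region, against the SAG's own contigs) are emitted unmapped.
#' Mismatch counts are substitution-only: sequencing errors falling inside
#' the aligned query interval, plus cell-vs-population SNPs inside the
#' aligned reference interval when aligning against a tiling of the
#' population genome (pass `variant_pos`).
#'
#' @param read_info Per-read truth table from [simulate_sag()].
#' @param contig_map Data frame with `contig_id`, `genome`, `start`, `end`
#'   (0-based half-open genome coordinates of each contig).
#' @param variant_pos Sorted 0-based genome positions (on `variant_genome`)
#'   where the reads' source cell differs from the tiled reference; counted
#'   into `nm`. Use the default empty vector when the tiling is the cell's
#'   own assembly.
#' @param variant_genome Genome id the `variant_pos` refer to.
#'
#' @return Data frame of alignment records: `read_id`, `mapped`, `primary`,
#'   `duplicate`, `target_id`, `pos` (1-based leftmost target coordinate),
#'   `cigar` (S/M operations only), `nm`, `read_length`, `reverse`.
#' @export
emit_alignments <- function(read_info, contig_map,
                            variant_pos = integer(0),
                            variant_genome = NA_character_) {
  n <- nrow(read_info)
  read_len <- read_info$read_length
  chim <- read_info$chimeric

  # the emitted arm: whole read, or the longer chimera arm
  len1 <- ifelse(chim, read_info$arm_split, read_len)
  len2 <- ifelse(chim, read_len - read_info$arm_split, 0L)
  use_arm2 <- chim & (len2 > len1)
  arm_s <- ifelse(use_arm2, read_info$a2_start, read_info$a1_start)
  arm_e <- ifelse(use_arm2, read_info$a2_end,
                  ifelse(chim, read_info$a1_start + len1, read_info$a1_end))
  # query offset where the emitted arm begins (arm1 -> 0, arm2 -> split)
  q0 <- ifelse(use_arm2, read_info$arm_split, 0L)

  target <- rep(NA_character_, n)
  pos <- rep(NA_integer_, n)
  cigar <- rep(NA_character_, n)
  nm <- rep(NA_integer_, n)
  ql <- rep(NA_integer_, n)   # aligned query interval, 0-based half-open
  qr <- rep(NA_integer_, n)

  for (g in unique(read_info$genome)) {
    cm <- contig_map[contig_map$genome == g, , drop = FALSE]
    sel <- which(read_info$genome == g)
    if (nrow(cm) == 0) next   # genome absent from tiling -> unmapped
    cm <- cm[order(cm$start), , drop = FALSE]
    s <- arm_s[sel]; e <- arm_e[sel]
    # contigs containing the arm's first and last base (0 = none / gap)
    locate <- function(x) {
      i <- findInterval(x, cm$start)
      i[i > 0 & x >= cm$end[pmax(i, 1L)]] <- 0L
      i
    }
    i1 <- locate(s)
    i2 <- locate(e - 1)
    ov1 <- ifelse(i1 > 0, pmin(e, cm$end[pmax(i1, 1L)]) - s, 0)
    ov2 <- ifelse(i2 > 0, e - pmax(s, cm$start[pmax(i2, 1L)]), 0)
    pick <- ifelse(ov1 >= ov2, i1, i2)
    pick[ov1 == 0 & ov2 == 0] <- 0L
    ok <- which(pick > 0)
    if (length(ok) == 0) next
    k <- pick[ok]
    as_ <- pmax(s[ok], cm$start[k])
    ae_ <- pmin(e[ok], cm$end[k])
    rows <- sel[ok]
    target[rows] <- cm$contig_id[k]
    pos[rows] <- as.integer(as_ - cm$start[k] + 1)
    rev_arm <- use_arm2[rows]
    # aligned query interval for forward arms: offset from arm start;
    # for inverted arms the genome right end maps to the query left end
    ql[rows] <- as.integer(ifelse(rev_arm,
                                  q0[rows] + (e[ok] - ae_),
                                  q0[rows] + (as_ - s[ok])))
    qr[rows] <- as.integer(ifelse(rev_arm,
                                  q0[rows] + (e[ok] - as_),
                                  q0[rows] + (ae_ - s[ok])))
    nm_snp <- 0L
    if (length(variant_pos) > 0 && identical(g, variant_genome)) {
      # count of variant_pos in [as_, ae_) via half-open findInterval
      nm_snp <- findInterval(ae_, variant_pos + 1) -
        findInterval(as_, variant_pos + 1)
    }
    nm[rows] <- nm_snp
  }

  mapped <- !is.na(target)
  # sequencing errors inside the aligned query interval
  errs <- read_info$errors
  for (i in which(mapped)) {
    ee <- errs[[i]]
    if (length(ee) > 0)
      nm[i] <- nm[i] + sum(ee >= ql[i] & ee < qr[i])
  }
  lclip <- ql
  rclip <- read_len - qr
  m <- qr - ql
  cigar[mapped] <- paste0(
    ifelse(lclip[mapped] > 0, paste0(lclip[mapped], "S"), ""),
    m[mapped], "M",
    ifelse(rclip[mapped] > 0, paste0(rclip[mapped], "S"), ""))

  data.frame(read_id = read_info$read_id,
             mapped = mapped,
             primary = TRUE,
             duplicate = FALSE,
             target_id = target,
             pos = pos,
             cigar = cigar,
             nm = ifelse(mapped, nm, NA_integer_),
             read_length = read_len,
             reverse = ifelse(mapped, use_arm2, NA),
             stringsAsFactors = FALSE)
}
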