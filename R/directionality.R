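#' Pair divergent TSRs into bidirectional units
#'
#' A plus-strand TSR pairs with a minus-strand TSR on the same chromosome
#' when the minus-strand major TSS lies 1..`pair_window` bp upstream of
#' the plus-strand major TSS (divergent geometry: the two transcripts face
#' away from each other). Each TSR takes at most one partner; candidate
#' pairs are accepted nearest-first, with ties resolved by higher combined
#' signal and then by TSR id, so matching is deterministic.
#'
#' @param tsrs TSR table.
#' @param pair_window maximum distance in bp between the paired major
#'   TSSs (default 275, mirroring the divergent context window).
#' @return data.frame `tsr_id,partner_id` with one row per TSR
#'   (`partner_id` `NA` when unpaired).
#' @export
pair_bidirectional <- function(tsrs, pair_window = 275L) {
  ids <- tsrs$id
  partner <- rep(NA_character_, nrow(tsrs))
  names(partner) <- ids
  plus <- which(tsrs$strand == "+")
  minus <- which(tsrs$strand == "-")
  cand <- NULL
  if (length(plus) > 0L && length(minus) > 0L) {
    p <- data.table::data.table(chrom = tsrs$chrom[plus], ppos = tsrs$major_tss[plus],
                                pid = ids[plus], pnorm = tsrs$total_norm[plus])
    m <- data.table::data.table(chrom = tsrs$chrom[minus], mpos = tsrs$major_tss[minus],
                                mid = ids[minus], mnorm = tsrs$total_norm[minus])
    m[, c("lo", "hi") := list(m$mpos + 1L, m$mpos + as.integer(pair_window))]
    cand <- p[m, on = c("chrom", "ppos>=lo", "ppos<=hi"), nomatch = NULL,
              list(pid = pid, mid = mid,
                   dist = x.ppos - mpos, signal = pnorm + mnorm)]
  }
  if (!is.null(cand) && nrow(cand) > 0L) {
    data.table::setorderv(cand, c("dist", "signal", "pid", "mid"),
                          order = c(1L, -1L, 1L, 1L))
    for (i in seq_len(nrow(cand))) {
      a <- cand$pid[i]; b <- cand$mid[i]
      if (is.na(partner[a]) && is.na(partner[b])) {
        partner[a] <- b
        partner[b] <- a
      }
    }
  }
  data.frame(tsr_id = ids, partner_id = unname(partner))
}

#' Assign initiation styles (S / U / US / UU)
#'
#' Combines pairing and stability into the four initiation styles:
#' unpaired stable TSRs are `S`, unpaired unstable TSRs are `U`; for a
#' divergent pair, an unstable TSR whose partner is also unstable is `UU`,
#' an unstable TSR with a stable partner is `US`, and a stable TSR is
#' reported `S` regardless of its partner (the bidirectional flag retains
#' the pairing).
#'
#' @param tsrs TSR table.
#' @param partners output of [pair_bidirectional()].
#' @param calls stability calls from [classify_stability()].
#' @return data.frame `tsr_id,style,partner_id,bidirectional`.
#' @export
assign_styles <- function(tsrs, partners, calls) {
  ids <- tsrs$id
  cls <- calls$class[match(ids, calls$tsr_id)]
  if (any(is.na(cls))) stop("every TSR needs a stability call")
  pid <- partners$partner_id[match(ids, partners$tsr_id)]
  partner_cls <- calls$class[match(pid, calls$tsr_id)]
  style <- ifelse(cls == "stable", "S",
           ifelse(is.na(pid), "U",
           ifelse(partner_cls == "unstable", "UU", "US")))
  data.frame(tsr_id = ids, style = style, partner_id = pid,
             bidirectional = !is.na(pid))
}

#' Fraction of TSRs initiating bidirectional unstable transcripts
#'
#' Reports the percentage of TSRs with style `UU` (unstable in both
#' directions — the vertebrate-enhancer-like configuration), the
#' percentage that are additionally distal (more than `distal_cutoff` bp
#' from the nearest annotated 5' end), and the distance distribution of
#' UU TSRs.
#'
#' @param styles output of [assign_styles()].
#' @param contexts output of [classify_context()] (uses the signed
#'   `distance` column; `NA` distances count as distal).
#' @param distal_cutoff distance threshold in bp.
#' @return list `pct_uu`, `pct_uu_distal`, `uu_distances` (abs distances
#'   of UU TSRs), `n`.
#' @export
bidirectional_unstable_fraction <- function(styles, contexts,
                                            distal_cutoff = 2000L) {
  n <- nrow(styles)
  if (n == 0L) return(list(pct_uu = NA_real_, pct_uu_distal = NA_real_,
                           uu_distances = numeric(0), n = 0L))
  uu <- styles$style == "UU"
  d <- abs(contexts$distance[match(styles$tsr_id, contexts$tsr_id)])
  distal <- is.na(d) | d > distal_cutoff
  list(pct_uu = 100 * sum(uu) / n,
       pct_uu_distal = 100 * sum(uu & distal) / n,
       uu_distances = d[uu],
       n = n)
}
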