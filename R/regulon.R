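# Regulon membership: the three expression criteria plus the
# operator-binding requirement, TU collapsing and early/late calls.

#' Call SOS regulon membership from three contrasts plus binding
#'
#' A gene is a regulon member when it satisfies all of: (1) induced in
#' damaged wild type at 40 min; (2) derepressed in the repressor
#' deletion without damage; (3) its damage induction is recA-dependent
#' (NOT induced in the recA deletion under damage); and (4) its
#' promoter is bound by the repressor. Genes that cannot show
#' derepression for technical reasons (e.g. deleted in the repressor
#' strain) can be forced through criterion 2 with an explicit override.
#'
#' @param de_wt40 DE table (from [run_contrast()]) for damaged wild
#'   type at 40 min vs untreated
#' @param de_dlexa DE table for repressor deletion vs wild type,
#'   no damage
#' @param de_dreca40 DE table for the recA deletion under damage at
#'   40 min vs untreated
#' @param lexa_bound character vector of gene ids with repressor
#'   binding at their promoter
#' @param overrides named character vector: names are gene ids whose
#'   criterion 2 is forced TRUE, values the recorded reason
#' @return data.frame: gene_id, c1_induced_wt40, c2_derepressed_dlexa,
#'   c3_recA_dependent, lexa_bound, member, override_reason
#' @export
call_sos_regulon <- function(de_wt40, de_dlexa, de_dreca40, lexa_bound,
                             overrides = character(0)) {
  ids <- de_wt40$gene_id
  for (other in list(de_dlexa, de_dreca40)) {
    miss <- union(setdiff(ids, other$gene_id), setdiff(other$gene_id, ids))
    if (length(miss)) {
      stop("gene universe mismatch between contrasts: ",
           paste(head(miss, 10), collapse = ", "))
    }
  }
  ind <- function(de) setNames(de$induced, de$gene_id)[ids]
  c1 <- unname(ind(de_wt40))
  c2 <- unname(ind(de_dlexa))
  c3 <- !unname(ind(de_dreca40))
  reason <- rep(NA_character_, length(ids))
  if (length(overrides)) {
    stopifnot(!is.null(names(overrides)))
    hit <- match(names(overrides), ids)
    if (anyNA(hit)) stop("override for unknown gene: ",
                         paste(names(overrides)[is.na(hit)], collapse = ", "))
    c2[hit] <- TRUE
    reason[hit] <- unname(overrides)
  }
  bound <- ids %in% lexa_bound
  data.frame(
    gene_id = ids, c1_induced_wt40 = c1, c2_derepressed_dlexa = c2,
    c3_recA_dependent = c3, lexa_bound = bound,
    member = c1 & c2 & c3 & bound, override_reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Collapse member genes to transcriptional units
#'
#' @param calls output of [call_sos_regulon()]
#' @param annotation annotation data.frame with gene_id, tu_id, strand,
#'   genes ordered in transcription direction within each TU
#' @return data.frame, one row per TU containing at least one member
#'   gene: tu_id, promoter_gene (first gene of the TU in transcription
#'   direction), n_member_genes, member_genes (comma-joined)
#' @export
collapse_to_tus <- function(calls, annotation) {
  members <- calls$gene_id[calls$member]
  idx <- match(members, annotation$gene_id)
  if (anyNA(idx)) stop("member genes missing from annotation: ",
                       paste(members[is.na(idx)], collapse = ", "))
  tus <- unique(annotation$tu_id[idx])
  out <- lapply(tus, function(tid) {
    rows <- annotation[annotation$tu_id == tid, , drop = FALSE]
    if (length(unique(rows$strand)) != 1) {
      stop("TU with mixed strands: ", tid)
    }
    mg <- intersect(rows$gene_id, members)
    data.frame(tu_id = tid, promoter_gene = rows$gene_id[1],
               n_member_genes = length(mg),
               member_genes = paste(mg, collapse = ","),
               stringsAsFactors = FALSE)
  })
  if (length(out) == 0) {
    return(data.frame(tu_id = character(), promoter_gene = character(),
                      n_member_genes = integer(), member_genes = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Classify regulon TUs as early or late
#'
#' A TU is early when any of its member genes is induced at 20 min of
#' damage, late when induction first appears at 40 min only. TUs with
#' no induction at either time are dropped with a warning.
#'
#' @param tus output of [collapse_to_tus()]
#' @param de_wt20,de_wt40 DE tables for 20 and 40 min damage contrasts
#' @param annotation annotation data.frame
#' @return data.frame: tu_id, promoter_gene, class ("early"/"late"),
#'   first_induced_timepoint (20 or 40)
#' @export
classify_temporal <- function(tus, de_wt20, de_wt40, annotation) {
  ind20 <- setNames(de_wt20$induced, de_wt20$gene_id)
  ind40 <- setNames(de_wt40$induced, de_wt40$gene_id)
  rows <- lapply(seq_len(nrow(tus)), function(i) {
    genes <- annotation$gene_id[annotation$tu_id == tus$tu_id[i]]
    if (anyNA(ind20[genes]) || anyNA(ind40[genes])) {
      stop("TU genes missing from a contrast: ", tus$tu_id[i])
    }
    e20 <- any(ind20[genes])
    e40 <- any(ind40[genes])
    if (!e20 && !e40) {
      warning("TU induced at neither timepoint, excluded: ", tus$tu_id[i])
      return(NULL)
    }
    data.frame(tu_id = tus$tu_id[i], promoter_gene = tus$promoter_gene[i],
               class = if (e20) "early" else "late",
               first_induced_timepoint = if (e20) 20L else 40L,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(data.frame(tu_id = character(), promoter_gene = character(),
                      class = character(),
                      first_induced_timepoint = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
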