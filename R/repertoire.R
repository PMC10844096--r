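#' Assemble per-cell clonotypes from receptor contigs
#'
#' Only productive chains are used. Within a cell, contigs that are exact
#' duplicates of the same (chain, V, J, CDR3-nt) tuple are collapsed keeping
#' the highest-UMI record (ties broken by lexical CDR3-nt); distinct tuples
#' on the same locus are all retained and flag the cell as `multi`. The
#' clonotype key is the canonical string over the sorted retained tuples, so
#' it is invariant to contig input order.
#'
#' Chain configuration: `paired` iff exactly one productive TRA and one TRB
#' (for B cells: one IGH plus one light chain); `single_alpha` /
#' `single_beta` when only one side is present; `multi` when any locus
#' retains more than one distinct chain.
#'
#' @param contigs contig table (see [read_contigs()]).
#' @return data.frame: barcode, key, chain_config, n_chains, trb_cdr3_nt
#'   (first TRB nucleotide CDR3, NA when absent). Cells without any
#'   productive chain are omitted.
#' @export
assemble_clonotypes <- function(contigs) {
  contigs <- validate_contigs(contigs)
  prod <- contigs[contigs$productive, , drop = FALSE]
  if (!nrow(prod))
    return(data.frame(barcode = character(), key = character(),
                      chain_config = character(), n_chains = integer(),
                      tra_cdr3_nt = character(), trb_cdr3_nt = character(),
                      stringsAsFactors = FALSE))
  # collapse exact duplicate tuples keeping highest umis, lexical cdr3_nt
  ord <- order(prod$barcode, prod$chain, prod$v_gene, prod$j_gene,
               prod$cdr3_nt, -prod$umis)
  prod <- prod[ord, , drop = FALSE]
  tuple <- paste(prod$barcode, prod$chain, prod$v_gene, prod$j_gene,
                 prod$cdr3_nt, sep = "\r")
  prod <- prod[!duplicated(tuple), , drop = FALSE]

  chain_str <- paste(prod$chain, prod$v_gene, prod$j_gene, prod$cdr3_nt,
                     sep = ":")
  by_cell <- split(seq_len(nrow(prod)), prod$barcode)
  res <- lapply(by_cell, function(idx) {
    ch <- prod$chain[idx]
    key <- paste(sort(chain_str[idx]), collapse = ";")
    n_tra <- sum(ch == "TRA"); n_trb <- sum(ch == "TRB")
    n_igh <- sum(ch == "IGH"); n_igl <- sum(ch %in% c("IGK", "IGL"))
    config <- if (any(table(ch) > 1) || (n_igl > 1)) "multi"
    else if (n_tra + n_trb > 0) {
      if (n_tra == 1 && n_trb == 1) "paired"
      else if (n_tra == 1 && n_trb == 0) "single_alpha"
      else if (n_tra == 0 && n_trb == 1) "single_beta"
      else "multi"
    } else {
      if (n_igh == 1 && n_igl == 1) "paired"
      else if (n_igh == 1) "single_beta"
      else "single_alpha"
    }
    trb <- prod$cdr3_nt[idx][ch == "TRB"]
    tra <- prod$cdr3_nt[idx][ch == "TRA"]
    data.frame(barcode = prod$barcode[idx][1], key = key,
               chain_config = config, n_chains = length(idx),
               tra_cdr3_nt = if (length(tra)) tra[1] else NA_character_,
               trb_cdr3_nt = if (length(trb)) trb[1] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Clone sizes per clonotype
#'
#' The number of cells expressing each clonotype key.
#'
#' @param assignments output of [assemble_clonotypes()].
#' @return data.frame key, size, sorted by decreasing size then key.
#' @export
clone_sizes <- function(assignments) {
  if (!nrow(assignments)) stop_named("empty_input_error", "no assignments")
  tab <- table(assignments$key)
  out <- data.frame(key = names(tab), size = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$size, out$key), , drop = FALSE]
}

#' Call major and minor tumor clonotypes by clonal fraction
#'
#' Clonotypes whose cell fraction is at least `min_major_fraction` are major
#' candidates; candidates sharing an identical nucleotide CDR3 on the same
#' locus are merged into one related-clone tumor group. This covers both the
#' study's related-clone behaviour (two clones with identical TCRβ chains
#' but differing TCRα) and the single-chain variants of a clone, which share
#' its remaining chain. The group with the largest summed fraction is the
#' sample's single major group. Clonotypes with fraction in
#' `[min_minor_fraction, min_major_fraction)` that share a chain with the
#' major group are labelled minor. All cells of major or minor clonotypes
#' are flagged tumor.
#'
#' @param assignments output of [assemble_clonotypes()] for one sample.
#' @param min_major_fraction fraction of assigned cells for a major
#'   candidate (default 0.05).
#' @param min_minor_fraction lower fraction bound for minor clones
#'   (default 0.01).
#' @return list: `clonotypes` (key, size, fraction, label, trb_cdr3_nt),
#'   `cells` (barcode, is_tumor), `tumor_fraction`,
#'   `related_groups` (list of key vectors sharing a TRB).
#' @export
call_tumor_clones <- function(assignments, min_major_fraction = 0.05,
                              min_minor_fraction = 0.01) {
  if (!nrow(assignments)) {
    warning("no clonotype assignments; empty tumor call")
    return(list(clonotypes = data.frame(), cells = data.frame(),
                tumor_fraction = 0, related_groups = list()))
  }
  sizes <- clone_sizes(assignments)
  n <- nrow(assignments)
  sizes$fraction <- sizes$size / n
  at <- match(sizes$key, assignments$key)
  sizes$tra_cdr3_nt <- assignments$tra_cdr3_nt[at]
  sizes$trb_cdr3_nt <- assignments$trb_cdr3_nt[at]
  # locus-tagged chain identities used for related-clone merging
  chain_ids <- function(i) {
    out <- c(if (!is.na(sizes$tra_cdr3_nt[i])) paste0("TRA:", sizes$tra_cdr3_nt[i]),
             if (!is.na(sizes$trb_cdr3_nt[i])) paste0("TRB:", sizes$trb_cdr3_nt[i]))
    out %||% character()
  }

  cand <- which(sizes$fraction >= min_major_fraction)
  sizes$label <- "none"
  related_groups <- list()
  if (length(cand)) {
    # group candidates connected through any identical same-locus CDR3
    grp <- seq_along(cand)
    ids <- lapply(cand, chain_ids)
    for (i in seq_along(cand)) for (j in seq_len(i - 1L)) {
      if (length(intersect(ids[[i]], ids[[j]])))
        grp[grp == grp[i]] <- grp[j]
    }
    gfrac <- tapply(sizes$fraction[cand], grp, sum)
    best <- names(gfrac)[order(-gfrac)][1]
    major_keys <- sizes$key[cand[grp == as.integer(best)]]
    sizes$label[sizes$key %in% major_keys] <- "major"
    major_ids <- unique(unlist(lapply(which(sizes$key %in% major_keys),
                                      chain_ids)))
    minor <- sizes$fraction >= min_minor_fraction &
      sizes$fraction < min_major_fraction &
      vapply(seq_len(nrow(sizes)),
             function(i) length(intersect(chain_ids(i), major_ids)) > 0,
             logical(1))
    sizes$label[minor] <- "minor"
    related_groups <- list(sizes$key[sizes$label %in% c("major", "minor")])
  }
  tumor_keys <- sizes$key[sizes$label != "none"]
  cells <- data.frame(barcode = assignments$barcode,
                      is_tumor = assignments$key %in% tumor_keys,
                      stringsAsFactors = FALSE)
  list(clonotypes = sizes, cells = cells,
       tumor_fraction = mean(cells$is_tumor),
       related_groups = related_groups)
}

#' Repertoire overlap between two cell groups
#'
#' @param keys_a,keys_b per-cell clonotype keys of the two groups.
#' @param method "public" (count of shared distinct keys), "jaccard"
#'   (|A∩B| / |A∪B| over key sets) or "morisita" (Morisita-Horn index on
#'   key frequency vectors, in \[0, 1\]).
#' @return numeric scalar.
#' @export
repertoire_overlap <- function(keys_a, keys_b,
                               method = c("public", "jaccard", "morisita")) {
  method <- match.arg(method)
  if (!length(keys_a) || !length(keys_b))
    stop_named("empty_group_error", "both groups must be nonempty")
  sa <- unique(keys_a); sb <- unique(keys_b)
  switch(method,
    public = length(intersect(sa, sb)),
    jaccard = length(intersect(sa, sb)) / length(union(sa, sb)),
    morisita = {
      keys <- union(sa, sb)
      p <- as.vector(table(factor(keys_a, keys))) / length(keys_a)
      q <- as.vector(table(factor(keys_b, keys))) / length(keys_b)
      denom <- sum(p^2) + sum(q^2)
      if (denom == 0) 0 else 2 * sum(p * q) / denom
    })
}

#' Clonotypes shared between two compartments
#'
#' @param assignments_a,assignments_b [assemble_clonotypes()] outputs for the
#'   two compartments (e.g., LN and PB).
#' @return data.frame key, size_a, size_b for keys present in both.
#' @export
cross_compartment_sharing <- function(assignments_a, assignments_b) {
  sa <- clone_sizes(assignments_a)
  sb <- clone_sizes(assignments_b)
  shared <- intersect(sa$key, sb$key)
  out <- data.frame(key = shared,
                    size_a = sa$size[match(shared, sa$key)],
                    size_b = sb$size[match(shared, sb$key)],
                    stringsAsFactors = FALSE)
  out[order(-(out$size_a + out$size_b), out$key), , drop = FALSE]
}
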