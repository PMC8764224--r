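#' Match free fatty acids to complex-lipid acyl chains
#'
#' Builds the table of exact acyl-chain matches between every free fatty acid
#' (FA) feature and complex lipids carrying the same `(carbons, double
#' bonds)` chain: acylcarnitines on their single chain, phosphatidylcholines
#' on the sn-2 chain (name order gives sn-1/sn-2; sum-composition PCs are
#' skipped), lysophospholipids (LPC/LPE/LPI/LPA) on their single chain, and
#' ceramides/sphingomyelins on the N-acyl chain. Matching requires exact
#' equality of carbons and double bonds; no tolerance matching. A
#' `very_long_chain` flag (>= 24 carbons) propagates from the fatty acid so
#' the divergent behaviour of C24:0/C26:0 species can be filtered on.
#'
#' @param x a [metabo_study()] (its parsed lipid descriptors are used), or a
#'   named list of `lipid_descriptor`s keyed by feature id.
#' @return data.frame with `fatty_acid_feature`, `partner_feature`,
#'   `partner_class`, `matched_carbons`, `matched_double_bonds`,
#'   `match_rule` (`same_chain`, `sn2` or `n_acyl`), `very_long_chain`.
#'   Zero rows when no FA parses.
#' @export
build_matches <- function(x) {
  lipids <- if (inherits(x, "metabo_study")) x$lipids else x
  stopifnot(is.list(lipids), !is.null(names(lipids)))
  lipids <- Filter(Negate(is.null), lipids)

  chain_of <- function(d) {
    switch(d$lipid_class,
      CAR = if (nrow(d$chains) == 1L) list(d$chains[1L, ], "same_chain"),
      LPC = , LPE = , LPI = , LPA =
        if (nrow(d$chains) == 1L) list(d$chains[1L, ], "same_chain"),
      PC = if (d$sn_resolved && nrow(d$chains) >= 2L)
        list(d$chains[2L, ], "sn2"),
      Cer = , SM = if (d$sn_resolved && nrow(d$chains) == 2L)
        list(d$chains[2L, ], "n_acyl"),
      NULL)
  }

  fas <- Filter(function(d) d$lipid_class == "FA" && nrow(d$chains) == 1L, lipids)
  if (!length(fas)) return(empty_matches())
  partners <- Filter(function(d) d$lipid_class != "FA", lipids)

  rows <- list()
  for (fa_id in sort(names(fas))) {
    fa_chain <- fas[[fa_id]]$chains[1L, ]
    for (p_id in sort(names(partners))) {
      hit <- chain_of(partners[[p_id]])
      if (is.null(hit)) next
      if (hit[[1L]]$carbons == fa_chain$carbons &&
          hit[[1L]]$double_bonds == fa_chain$double_bonds) {
        rows[[length(rows) + 1L]] <- data.frame(
          fatty_acid_feature = fa_id, partner_feature = p_id,
          partner_class = partners[[p_id]]$lipid_class,
          matched_carbons = fa_chain$carbons,
          matched_double_bonds = fa_chain$double_bonds,
          match_rule = hit[[2L]],
          very_long_chain = fa_chain$carbons >= 24L)
      }
    }
  }
  if (!length(rows)) return(empty_matches())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_matches <- function() {
  data.frame(fatty_acid_feature = character(), partner_feature = character(),
             partner_class = character(), matched_carbons = integer(),
             matched_double_bonds = integer(), match_rule = character(),
             very_long_chain = logical())
}

#' Co-variation of matched fatty acid / complex lipid effects
#'
#' For every chain match and every intervention, pairs the group mean log2
#' fold change of the fatty acid with that of its partner lipid (one scatter
#' point per match per intervention) and computes the Pearson correlation per
#' partner class over the pooled points; lysophospholipid subclasses are also
#' pooled into a combined `lyso` row. Classes with fewer than 3 points get
#' `r = NA`.
#'
#' @param matches a [build_matches()] table.
#' @param means a [mean_fold_changes()] table covering both members of every
#'   match.
#' @return list with `points` (match x intervention scatter rows: adds
#'   `group`, `fa_log2fc`, `partner_log2fc` to the match columns) and
#'   `class_r` (partner_class, n, r, p).
#' @export
match_covariation <- function(matches, means) {
  if (!nrow(matches)) {
    return(list(points = cbind(matches, group = character(),
                               fa_log2fc = numeric(), partner_log2fc = numeric()),
                class_r = data.frame(partner_class = character(), n = integer(),
                                     r = numeric(), p = numeric())))
  }
  key <- paste(means$feature_id, means$group)
  lookup <- stats::setNames(means$mean, key)
  groups <- unique(means$group)

  pts <- do.call(rbind, lapply(groups, function(g) {
    fa <- lookup[paste(matches$fatty_acid_feature, g)]
    pa <- lookup[paste(matches$partner_feature, g)]
    cbind(matches, group = g, fa_log2fc = unname(fa),
          partner_log2fc = unname(pa))
  }))
  pts <- pts[stats::complete.cases(pts$fa_log2fc, pts$partner_log2fc), ,
             drop = FALSE]
  rownames(pts) <- NULL

  class_sets <- c(stats::setNames(as.list(unique(pts$partner_class)),
                                  unique(pts$partner_class)),
                  list(lyso = c("LPC", "LPE", "LPI", "LPA")))
  class_r <- do.call(rbind, lapply(names(class_sets), function(nm) {
    sub <- pts[pts$partner_class %in% class_sets[[nm]], , drop = FALSE]
    if (nrow(sub) < 3L) {
      return(data.frame(partner_class = nm, n = nrow(sub), r = NA_real_,
                        p = NA_real_))
    }
    tst <- suppressWarnings(stats::cor.test(sub$fa_log2fc, sub$partner_log2fc))
    data.frame(partner_class = nm, n = nrow(sub), r = unname(tst$estimate),
               p = tst$p.value)
  }))
  class_r <- class_r[class_r$n > 0L, , drop = FALSE]
  rownames(class_r) <- NULL
  list(points = pts, class_r = class_r)
}
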