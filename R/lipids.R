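lipid_classes <- function() {
  c("FA", "CAR", "TG", "PC", "PE", "LPA", "LPC", "LPE", "LPI", "Cer", "SM")
}

lipid_class_of <- function(metabolite_class) {
  # map free-text metabolite classes to shorthand class tokens where 1:1
  switch(tolower(metabolite_class),
         "fatty acid" = "FA",
         "acylcarnitine" = "CAR",
         "triacylglycerol" = "TG",
         "phosphatidylcholine" = "PC",
         "ceramide" = "Cer",
         "sphingomyelin" = "SM",
         NA_character_)
}

#' Parse lipid shorthand nomenclature
#'
#' Parses names of the form `CLASS(c1:d1/c2:d2/...)` or `CLASS(c:d)` into a
#' structured descriptor. Supported class tokens (matched case-insensitively
#' and normalised to their canonical form) are FA, CAR, TG, PC, PE, LPA, LPC,
#' LPE, LPI, Cer and SM. Sphingolipid backbone chains carry the `d` prefix
#' (e.g. `SM(d18:1/18:0)`) and are flagged as sphingoid. A name with `/`
#' separators has its individual sn positions resolved; a sum-composition name
#' such as `TG(48:1)` is parsed with `sn_resolved = FALSE` and is therefore
#' excluded from chain matching.
#'
#' Unparseable names are a soft failure: the function warns and returns
#' `NULL`, so the feature is retained without a descriptor.
#'
#' @param name character scalar, the shorthand name.
#' @param feature_id optional id used in the warning message.
#' @return A `lipid_descriptor` (list with `lipid_class`, `chains` — a
#'   data.frame with columns `carbons`, `double_bonds`, `sphingoid` — and
#'   `sn_resolved`), or `NULL` when the name does not parse.
#' @seealso [format_lipid_name()] for the inverse.
#' @export
#' @examples
#' parse_lipid_name("PC(16:0/20:4)")
#' parse_lipid_name("TG(48:1)")$sn_resolved
parse_lipid_name <- function(name, feature_id = NULL) {
  soft_fail <- function(why) {
    warning("lipid name ", if (!is.null(feature_id)) paste0("for feature '", feature_id, "' "),
            "'", name, "' not parseable (", why, "); feature kept without descriptor",
            call. = FALSE)
    NULL
  }
  if (!is.character(name) || length(name) != 1L || is.na(name)) {
    return(soft_fail("not a character scalar"))
  }
  m <- regmatches(name, regexec("^\\s*([A-Za-z]+)\\(([^()]*)\\)\\s*$", name))[[1L]]
  if (length(m) != 3L) return(soft_fail("not of the form CLASS(...)"))
  cls_idx <- match(toupper(m[2L]), toupper(lipid_classes()))
  if (is.na(cls_idx)) return(soft_fail(paste0("unknown class token '", m[2L], "'")))
  cls <- lipid_classes()[cls_idx]

  sn_resolved <- grepl("/", m[3L], fixed = TRUE)
  chain_str <- strsplit(m[3L], "/", fixed = TRUE)[[1L]]
  if (!length(chain_str) || any(!nzchar(chain_str))) {
    return(soft_fail("empty chain specification"))
  }
  cm <- regmatches(chain_str, regexec("^(d?)([0-9]+):([0-9]+)$", chain_str))
  if (any(lengths(cm) != 4L)) return(soft_fail("chain not of the form [d]C:D"))
  chains <- data.frame(
    carbons = as.integer(vapply(cm, `[`, "", 3L)),
    double_bonds = as.integer(vapply(cm, `[`, "", 4L)),
    sphingoid = vapply(cm, `[`, "", 2L) == "d"
  )
  if (any(chains$carbons < 2L * chains$double_bonds)) {
    return(soft_fail("carbons < 2 x double bonds"))
  }
  if (cls %in% c("Cer", "SM") && sn_resolved) {
    if (nrow(chains) != 2L || !chains$sphingoid[1L]) {
      return(soft_fail("sphingolipids need a sphingoid base plus one N-acyl chain"))
    }
  }
  if (any(chains$sphingoid) && !cls %in% c("Cer", "SM")) {
    return(soft_fail("'d' prefix only valid for sphingolipids"))
  }
  structure(list(lipid_class = cls, chains = chains, sn_resolved = sn_resolved),
            class = "lipid_descriptor")
}

#' Format a lipid descriptor back to shorthand
#'
#' Inverse of [parse_lipid_name()]: `parse_lipid_name(format_lipid_name(d))`
#' reproduces `d` for every valid descriptor.
#'
#' @param d a `lipid_descriptor`.
#' @return character scalar shorthand name.
#' @export
format_lipid_name <- function(d) {
  stopifnot(inherits(d, "lipid_descriptor"))
  sep <- if (d$sn_resolved) "/" else stop_if_multi(d)
  chains <- paste0(ifelse(d$chains$sphingoid, "d", ""),
                   d$chains$carbons, ":", d$chains$double_bonds)
  paste0(d$lipid_class, "(", paste(chains, collapse = "/"), ")")
}

stop_if_multi <- function(d) {
  if (nrow(d$chains) > 1L) {
    stop("descriptor with several chains must be sn-resolved")
  }
  "/"
}

#' @export
print.lipid_descriptor <- function(x, ...) {
  cat(format_lipid_name(x),
      if (x$sn_resolved) " [sn-resolved]" else " [sum composition]", "\n", sep = "")
  invisible(x)
}
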