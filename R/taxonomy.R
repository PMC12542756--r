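## Minimal taxonomy support: lineage resolution against an NCBI-style
## node table, with a designated host clade (Chordata by default, taxid
## 7711 in the NCBI taxonomy).

#' Build a taxonomy table
#'
#' @param nodes data.frame with columns `taxid`, `parent_taxid`, `rank`,
#'   `name`. The root node is its own parent.
#' @param host_clade taxid of the clade whose members count as host
#'   (default 7711, Chordata).
#' @return an object of class `taxonomy_table`.
#' @export
taxonomy_table <- function(nodes, host_clade = 7711L) {
  req <- c("taxid", "parent_taxid", "rank", "name")
  if (!all(req %in% names(nodes))) {
    stop("nodes must have columns: ", paste(req, collapse = ", "))
  }
  nodes$taxid <- as.integer(nodes$taxid)
  nodes$parent_taxid <- as.integer(nodes$parent_taxid)
  if (anyDuplicated(nodes$taxid)) stop("duplicate taxids in node table")
  if (!host_clade %in% nodes$taxid) {
    stop("host clade taxid ", host_clade, " absent from taxonomy")
  }
  parent <- setNames(nodes$parent_taxid, as.character(nodes$taxid))
  # verify chains terminate at a root (node that is its own parent)
  for (t in nodes$taxid) {
    seen <- integer(0)
    cur <- t
    repeat {
      p <- parent[[as.character(cur)]]
      if (is.null(p) || is.na(p)) stop("parent of taxid ", cur, " missing from table")
      if (p == cur) break
      if (cur %in% seen) stop("taxonomy contains a cycle at taxid ", cur)
      seen <- c(seen, cur)
      cur <- p
    }
  }
  structure(
    list(nodes = nodes, parent = parent,
         name = setNames(nodes$name, as.character(nodes$taxid)),
         host_clade = as.integer(host_clade)),
    class = "taxonomy_table"
  )
}

#' Lineage of a taxid (inclusive, towards the root)
#' @param taxonomy a `taxonomy_table`.
#' @param taxid single taxid.
#' @return integer vector from `taxid` up to the root.
#' @export
lineage <- function(taxonomy, taxid) {
  stopifnot(inherits(taxonomy, "taxonomy_table"))
  key <- as.character(taxid)
  if (!key %in% names(taxonomy$parent)) {
    stop("taxid ", taxid, " absent from taxonomy")
  }
  out <- integer(0)
  cur <- as.integer(taxid)
  repeat {
    out <- c(out, cur)
    p <- taxonomy$parent[[as.character(cur)]]
    if (p == cur) break
    cur <- p
  }
  out
}

#' Test clade membership for a vector of taxids
#'
#' A taxid is in the clade when the clade taxid appears anywhere in its
#' lineage (inclusive: the clade node itself is a member).
#'
#' @param taxonomy a `taxonomy_table`.
#' @param taxids integer vector.
#' @param clade clade taxid; defaults to the taxonomy's host clade.
#' @return logical vector.
#' @export
in_clade <- function(taxonomy, taxids, clade = taxonomy$host_clade) {
  stopifnot(inherits(taxonomy, "taxonomy_table"))
  uniq <- unique(taxids)
  memb <- vapply(uniq, function(t) clade %in% lineage(taxonomy, t), logical(1))
  memb[match(taxids, uniq)]
}

#' Read NCBI-style nodes.dmp / names.dmp into a taxonomy table
#'
#' Accepts the classic `\t|\t`-separated dump format. Only scientific
#' names are kept from `names.dmp`.
#'
#' @param nodes_path path to nodes.dmp.
#' @param names_path path to names.dmp.
#' @param host_clade host clade taxid (default Chordata, 7711).
#' @return a `taxonomy_table`.
#' @export
read_taxonomy_dmp <- function(nodes_path, names_path, host_clade = 7711L) {
  split_dmp <- function(lines) {
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t|\t", fixed = TRUE)
  }
  np <- split_dmp(readLines(nodes_path))
  nodes <- data.frame(
    taxid = as.integer(vapply(np, `[[`, character(1), 1L)),
    parent_taxid = as.integer(vapply(np, `[[`, character(1), 2L)),
    rank = vapply(np, `[[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
  nm <- split_dmp(readLines(names_path))
  keep <- vapply(nm, function(p) length(p) >= 4 && p[[4]] == "scientific name", logical(1))
  nm <- nm[keep]
  names_df <- data.frame(
    taxid = as.integer(vapply(nm, `[[`, character(1), 1L)),
    name = vapply(nm, `[[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
  nodes$name <- names_df$name[match(nodes$taxid, names_df$taxid)]
  nodes$name[is.na(nodes$name)] <- paste0("taxid:", nodes$taxid[is.na(nodes$name)])
  taxonomy_table(nodes, host_clade = host_clade)
}
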