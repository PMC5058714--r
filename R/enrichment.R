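# Stage 2: hypergeometric enrichment of the DE genes against gene-set
# collections, and oncomodule assembly with the raw-p add-back rule.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= overlap)` for `X ~ Hypergeometric(universe, term, query)`: the
#' enrichment p-value of observing at least `overlap` query genes inside a
#' term of size `term` when `query` genes are drawn from `universe`.
#'
#' @param overlap Observed intersection size(s); may be a vector.
#' @param query Query (DE) set size.
#' @param term Term (gene-set) size within the universe.
#' @param universe Universe size.
#' @return The upper-tail probability (vectorized over `overlap`).
#' @export
hypergeometric_tail <- function(overlap, query, term, universe) {
  stop_if(any(c(overlap, query, term, universe) < 0) ||
            any(overlap > min(query, term)) || query > universe ||
            term > universe,
          "inconsistent counts: need 0 <= overlap <= min(query, term) <= universe")
  stats::phyper(overlap - 1, term, universe - term, query, lower.tail = FALSE)
}

#' Enrichment of a DE gene set against one collection
#'
#' Each set is intersected with the universe (the genes actually tested for
#' differential expression) before testing; sets with an empty intersection
#' are reported with p = 1.  BH correction is applied within the collection.
#'
#' @param de_set Character vector of DE genes (must lie inside `universe`).
#' @param collection A `gene_set_collection`.
#' @param universe Character vector: the tested gene universe.
#' @param alpha Adjusted-p significance cutoff (default 0.05).
#' @return An `enrichment_table`: data frame with columns `collection`,
#'   `category`, `set`, `query`, `term`, `overlap`, `raw_p`, `adj_p`,
#'   `significant`.
#' @export
enrich_collection <- function(de_set, collection, universe, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  stop_if(length(universe) == 0, "empty universe")
  extra <- setdiff(de_set, universe)
  stop_if(length(extra) > 0,
          sprintf("de_set contains genes outside the universe: %s...",
                  paste(utils::head(extra, 3), collapse = ", ")))
  q <- length(de_set)
  N <- length(universe)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], universe)
    t_ <- length(members)
    k <- length(intersect(de_set, members))
    p <- if (t_ == 0) 1 else hypergeometric_tail(k, q, t_, N)
    data.frame(collection = collection$name, category = collection$category,
               set = nm, query = q, term = t_, overlap = k, raw_p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$raw_p, "BH")
  out$significant <- out$adj_p < alpha
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Enrichment across several collections
#'
#' @inheritParams enrich_collection
#' @param collections List of `gene_set_collection`s.
#' @param bh_scope `"collection"` (BH within each collection, default) or
#'   `"pooled"` (one BH family across all collections).
#' @return Combined `enrichment_table`.
#' @export
enrich_collections <- function(de_set, collections, universe, alpha = 0.05,
                               bh_scope = c("collection", "pooled")) {
  bh_scope <- match.arg(bh_scope)
  tabs <- lapply(collections, enrich_collection, de_set = de_set,
                 universe = universe, alpha = alpha)
  out <- do.call(rbind, tabs)
  if (bh_scope == "pooled") {
    out$adj_p <- stats::p.adjust(out$raw_p, "BH")
    out$significant <- out$adj_p < alpha
  }
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  attr(out, "bh_scope") <- bh_scope
  out
}

#' Assemble oncomodules from significant gene sets
#'
#' One oncomodule per significant set.  Members are the set's genes (inside
#' the tested universe) with a differential-expression raw p below
#' `addback_raw_alpha` — this recovers genes discarded by the multiple-test
#' correction ("add-back"); since BH-adjusted p-values are never below raw
#' p-values, every DE member of the set is retained.  Members are split into
#' up- and down-regulated subsets; members with direction `"none"` are
#' dropped from both subsets with a message.  The controller gene (for the
#' knock-down evidence layer) is assigned only to sets of `tf_targets`
#' collections.
#'
#' @param enrichment An `enrichment_table` computed on `detable`'s DE set.
#' @param detable The `de_table` used for the enrichment query.
#' @param collections The list of `gene_set_collection`s tested.
#' @param addback_raw_alpha Raw-p add-back cutoff (default 0.05).
#' @return List of `oncomodule` objects (possibly empty), each a list with
#'   `name`, `collection`, `category`, `controller` (or `NA`), `up_set`,
#'   `down_set`.
#' @export
assemble_oncomodules <- function(enrichment, detable, collections,
                                 addback_raw_alpha = 0.05) {
  stopifnot(inherits(enrichment, "enrichment_table"),
            inherits(detable, "de_table"))
  by_name <- stats::setNames(collections,
                             vapply(collections, `[[`, "", "name"))
  sig <- enrichment[enrichment$significant, , drop = FALSE]
  loose <- detable$gene[detable$raw_p < addback_raw_alpha]
  modules <- lapply(seq_len(nrow(sig)), function(i) {
    col <- by_name[[sig$collection[i]]]
    set_name <- sig$set[i]
    members <- intersect(intersect(col$sets[[set_name]], detable$gene), loose)
    dirs <- detable$direction[match(members, detable$gene)]
    n_none <- sum(dirs == "none")
    if (n_none > 0)
      message(sprintf(
        "assemble_oncomodules: %d member(s) of '%s' have no direction; dropped",
        n_none, set_name))
    if (length(members) > 0 && all(dirs == "none"))
      warning(sprintf("oncomodule '%s' has only direction-less members",
                      set_name))
    controller <- NA_character_
    if (col$category == "tf_targets" && !is.null(col$controllers) &&
        set_name %in% names(col$controllers))
      controller <- unname(col$controllers[[set_name]])
    structure(list(name = set_name, collection = col$name,
                   category = col$category, controller = controller,
                   up_set = sort(members[dirs == "up"]),
                   down_set = sort(members[dirs == "down"])),
              class = "oncomodule")
  })
  names(modules) <- sig$set
  modules
}

#' @export
print.oncomodule <- function(x, ...) {
  cat(sprintf("oncomodule '%s' [%s/%s]: %d up, %d down%s\n",
              x$name, x$collection, x$category,
              length(x$up_set), length(x$down_set),
              if (is.na(x$controller)) "" else
                sprintf(", controller %s", x$controller)))
  invisible(x)
}

#' Write oncomodules as GMT (two lines per module: up and down subsets)
#'
#' @param modules List of `oncomodule`s.
#' @param path Output path.
#' @export
write_oncomodules <- function(modules, path) {
  sets <- list()
  for (m in modules) {
    if (length(m$up_set) > 0) sets[[paste0(m$name, "_up")]] <- m$up_set
    if (length(m$down_set) > 0) sets[[paste0(m$name, "_down")]] <- m$down_set
  }
  write_gene_sets(sets, path)
}
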