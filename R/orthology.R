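#' Greedy one-to-one ortholog matching for a species pair
#'
#' Reduces many-to-many ortholog candidate edges between two species to a
#' one-to-one mapping: edges are ranked in decreasing order of percent
#' identity (ties broken lexicographically on the two gene identifiers, for
#' determinism) and an edge is accepted if and only if neither endpoint
#' already has an accepted edge.
#'
#' @param edges Tibble/data frame with columns `gene_a`, `species_a`,
#'   `gene_b`, `species_b`, `percent_identity`. All rows must connect the
#'   same (unordered) species pair.
#' @return Tibble of accepted edges, same columns, in acceptance order.
#' @export
greedy_pairwise_map <- function(edges) {
  edges <- tibble::as_tibble(edges)
  check_edge_cols(edges)
  if (nrow(edges) == 0) return(edges)
  pr <- unique(pair_key(edges$species_a, edges$species_b))
  if (length(pr) != 1) {
    stop("edges mix species pairs: ", paste(pr, collapse = ", "), call. = FALSE)
  }
  ord <- order(-edges$percent_identity, edges$gene_a, edges$gene_b)
  edges <- edges[ord, , drop = FALSE]
  used_a <- character(0); used_b <- character(0)
  keep <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    if (!(edges$gene_a[i] %in% used_a) && !(edges$gene_b[i] %in% used_b)) {
      keep[i] <- TRUE
      used_a <- c(used_a, edges$gene_a[i])
      used_b <- c(used_b, edges$gene_b[i])
    }
  }
  edges[keep, , drop = FALSE]
}

check_edge_cols <- function(edges) {
  need <- c("gene_a", "species_a", "gene_b", "species_b", "percent_identity")
  miss <- setdiff(need, names(edges))
  if (length(miss) > 0) {
    stop("edge table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(edges$species_a == edges$species_b)) {
    stop("within-species edges are not allowed", call. = FALSE)
  }
  invisible(edges)
}

pair_key <- function(sa, sb) {
  paste(pmin(sa, sb), pmax(sa, sb), sep = "|")
}

# gene ids are made unique across species by prefixing the species label
vertex_id <- function(gene, species) paste(species, gene, sep = ":")

#' Fill missing orthologs through transitivity triangles
#'
#' Augments the reduced graph `G'` (built from hub-species pairwise maps)
#' with transitive edges: if apex gene A has an accepted edge to B, B is
#' matched to C in the independent pairwise map between `s(B)` and `s(C)`,
#' and C is untouched by `G'`, then the edge A--C can be added. Species
#' pairs `{s(B), s(C)}` are processed in the declared order; within a pair,
#' candidate triangles are sorted by the B--C percent identity (descending,
#' ties lexicographic on gene ids) and added greedily. An addition is
#' skipped if meanwhile C was linked or A acquired a neighbor in `s(C)`, so
#' every vertex keeps at most one neighbor per other species.
#'
#' @param gprime Accepted-edge tibble (as from [greedy_pairwise_map()],
#'   rows from all hub pairs combined).
#' @param pair_maps Named list of pairwise-map tibbles for the non-hub
#'   species pairs; names are `"A|B"` with the two species sorted.
#' @param species_order List of length-2 character vectors: the `{s(B),
#'   s(C)}` pairs in processing order.
#' @param apex Apex species label `s(A)`.
#' @return `gprime` with transitive edges appended (their
#'   `percent_identity` is the B--C score; column `transitive` marks them).
#' @export
fill_transitive <- function(gprime, pair_maps, species_order, apex) {
  gprime <- tibble::as_tibble(gprime)
  if (!"transitive" %in% names(gprime) && nrow(gprime) > 0) {
    gprime$transitive <- FALSE
  }
  touched <- unique(c(vertex_id(gprime$gene_a, gprime$species_a),
                      vertex_id(gprime$gene_b, gprime$species_b)))
  # neighbor species occupied per vertex
  nb_key <- c(paste(vertex_id(gprime$gene_a, gprime$species_a), gprime$species_b),
              paste(vertex_id(gprime$gene_b, gprime$species_b), gprime$species_a))

  for (pair in species_order) {
    if (apex %in% pair) next  # B and C must both differ from the apex
    key <- pair_key(pair[1], pair[2])
    pm <- pair_maps[[key]]
    if (is.null(pm)) {
      stop("missing pairwise map for species pair ", key, call. = FALSE)
    }
    # orient: each pair-map edge considered in both (B, C) directions
    pm2 <- tibble::tibble(
      gene_b = c(pm$gene_a, pm$gene_b),
      species_b = c(pm$species_a, pm$species_b),
      gene_c = c(pm$gene_b, pm$gene_a),
      species_c = c(pm$species_b, pm$species_a),
      percent_identity = c(pm$percent_identity, pm$percent_identity)
    )
    # apex edges A--B with s(B) in the pair
    ap_a <- gprime[gprime$species_a == apex & gprime$species_b %in% pair, ,
                   drop = FALSE]
    ap_b <- gprime[gprime$species_b == apex & gprime$species_a %in% pair, ,
                   drop = FALSE]
    ab <- tibble::tibble(
      gene_a = c(ap_a$gene_a, ap_b$gene_b),
      gene_b = c(ap_a$gene_b, ap_b$gene_a),
      species_b = c(ap_a$species_b, ap_b$species_a)
    )
    cand <- dplyr::inner_join(ab, pm2, by = c("gene_b", "species_b"))
    if (nrow(cand) == 0) next
    cand <- cand[order(-cand$percent_identity, cand$gene_b, cand$gene_c), ,
                 drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      cv <- vertex_id(cand$gene_c[i], cand$species_c[i])
      av <- vertex_id(cand$gene_a[i], apex)
      if (cv %in% touched) next
      if (paste(av, cand$species_c[i]) %in% nb_key) next
      gprime <- dplyr::bind_rows(gprime, tibble::tibble(
        gene_a = cand$gene_a[i], species_a = apex,
        gene_b = cand$gene_c[i], species_b = cand$species_c[i],
        percent_identity = cand$percent_identity[i], transitive = TRUE
      ))
      touched <- c(touched, cv)
      nb_key <- c(nb_key, paste(av, cand$species_c[i]),
                  paste(cv, apex))
    }
  }
  gprime
}

#' Build a one-to-one cross-species ortholog table
#'
#' Runs the full reconciliation: greedy one-to-one matching between the hub
#' species and every other species (forming `G'`), greedy matching for each
#' non-hub species pair, then transitive triangle filling anchored at the
#' apex species. Emits one row per ortholog tuple with one column per
#' species.
#'
#' @param edges Candidate edge table (`gene_a`, `species_a`, `gene_b`,
#'   `species_b`, `percent_identity`).
#' @param hub Hub species reconciled against every other species.
#' @param apex Apex species for transitive filling. Default: `"human"` when
#'   present among the species, otherwise the hub. Use `"none"` to skip
#'   transitive filling.
#' @param species_order Processing order of `{s(B), s(C)}` pairs for
#'   transitive filling, as a list of length-2 character vectors; default is
#'   all pairs with the hub first, then the remaining species
#'   alphabetically.
#' @param score_threshold Optional minimum percent identity; edges below it
#'   are discarded up front.
#' @return List with `table` (tibble: one column per species plus
#'   `transitive`), `graph` (the augmented `G'` edge tibble).
#' @export
build_one_to_one <- function(edges, hub, apex = NULL, species_order = NULL,
                             score_threshold = NULL) {
  edges <- tibble::as_tibble(edges)
  check_edge_cols(edges)
  species <- sort(unique(c(edges$species_a, edges$species_b)))
  if (!hub %in% species) stop("unknown hub species: ", hub, call. = FALSE)
  if (is.null(apex)) apex <- if ("human" %in% species) "human" else hub
  if (!identical(apex, "none") && !apex %in% species) {
    stop("unknown apex species: ", apex, call. = FALSE)
  }
  if (!is.null(score_threshold)) {
    edges <- edges[edges$percent_identity >= score_threshold, , drop = FALSE]
  }
  key <- pair_key(edges$species_a, edges$species_b)

  others <- setdiff(species, hub)
  gprime <- dplyr::bind_rows(lapply(others, function(s) {
    sub <- edges[key == pair_key(hub, s), , drop = FALSE]
    greedy_pairwise_map(sub)
  }))
  if (nrow(gprime) > 0) gprime$transitive <- FALSE

  if (!identical(apex, "none") && length(species) > 2) {
    all_pairs <- utils::combn(species, 2, simplify = FALSE)
    pair_maps <- stats::setNames(
      lapply(all_pairs, function(pr) {
        sub <- edges[key == pair_key(pr[1], pr[2]), , drop = FALSE]
        greedy_pairwise_map(sub)
      }),
      vapply(all_pairs, function(pr) pair_key(pr[1], pr[2]), "")
    )
    if (is.null(species_order)) {
      rest <- setdiff(species, hub)
      species_order <- c(lapply(rest, function(s) c(hub, s)),
                         utils::combn(rest, 2, simplify = FALSE))
    }
    gprime <- fill_transitive(gprime, pair_maps, species_order, apex)
  }

  list(table = components_to_table(gprime, species, hub), graph = gprime)
}

# Union-find over the edge list; one output row per connected component.
components_to_table <- function(gprime, species, hub) {
  if (nrow(gprime) == 0) {
    out <- tibble::as_tibble(stats::setNames(
      rep(list(character(0)), length(species)), species))
    out$transitive <- logical(0)
    return(out)
  }
  va <- vertex_id(gprime$gene_a, gprime$species_a)
  vb <- vertex_id(gprime$gene_b, gprime$species_b)
  verts <- unique(c(va, vb))
  parent <- stats::setNames(seq_along(verts), verts)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (j in seq_along(va)) {
    ra <- find(match(va[j], verts)); rb <- find(match(vb[j], verts))
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_along(verts), find, 0L)
  vspecies <- sub(":.*$", "", verts)
  vgene <- sub("^[^:]*:", "", verts)
  hub_adjacent <- verts %in% c(va[gprime$species_b == hub | gprime$species_a == hub],
                               vb[gprime$species_a == hub | gprime$species_b == hub])
  comp_has_trans <- tapply(
    c(gprime$transitive, gprime$transitive),
    vapply(c(match(va, verts), match(vb, verts)), find, 0L),
    any)

  split_idx <- split(seq_along(verts), roots)
  rows <- lapply(split_idx, function(ix) {
    vals <- stats::setNames(rep(NA_character_, length(species)), species)
    for (sp in unique(vspecies[ix])) {
      cand <- ix[vspecies[ix] == sp]
      # prefer the gene adjacent to a hub gene, then lexicographic
      cand <- cand[order(-hub_adjacent[cand], vgene[cand])]
      vals[sp] <- vgene[cand[1]]
    }
    tibble::as_tibble(as.list(vals))
  })
  out <- dplyr::bind_rows(rows)
  out$transitive <- as.logical(comp_has_trans[names(split_idx)])
  hub_gene <- out[[hub]]
  out[order(is.na(hub_gene), hub_gene), , drop = FALSE]
}

#' Translate a count matrix between species via an ortholog table
#'
#' Renames the gene axis of a cells-by-genes matrix from source-species to
#' target-species identifiers using a one-to-one ortholog table; genes
#' without a mapping are dropped, values are untouched.
#'
#' @param counts Cells-by-genes matrix with source-species gene column
#'   names.
#' @param table Ortholog table with one column per species (as from
#'   [build_one_to_one()]).
#' @param source,target Species column names in `table`.
#' @return The submatrix of mapped genes with target-species column names.
#' @export
translate_matrix <- function(counts, table, source, target) {
  if (!all(c(source, target) %in% names(table))) {
    stop("ortholog table lacks species column(s)", call. = FALSE)
  }
  map <- table[!is.na(table[[source]]) & !is.na(table[[target]]),
               c(source, target)]
  if (anyDuplicated(map[[target]]) || anyDuplicated(map[[source]])) {
    stop("ortholog table is not one-to-one for ", source, " -> ", target,
         call. = FALSE)
  }
  keep <- intersect(colnames(counts), map[[source]])
  out <- counts[, keep, drop = FALSE]
  colnames(out) <- map[[target]][match(keep, map[[source]])]
  out
}
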