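# Heterogeneous miRNA-centred regulatory network model.
#
# A network couples three biological layers: miRNAs targeting disease-
# associated proteins (directed, experimentally verified), transcription
# factors predicted to regulate miRNAs through promoter binding sites
# (directed), and protein-protein interactions among the retained proteins
# (undirected). Nodes carry one or more roles; miRNA identifiers live in a
# namespace disjoint from protein identifiers.

split_roles <- function(roles) strsplit(roles, ",", fixed = TRUE)

join_roles <- function(role_list) {
  vapply(role_list, function(r) paste(sort(unique(r)), collapse = ","), "")
}

#' Construct a regulatory network object
#'
#' Low-level constructor assembling a network from already-validated node and
#' edge tables. Most users should call [build_network()] instead, which
#' derives both tables from raw association tables. Nodes are sorted by
#' identifier and edges by (type, source, target); undirected PPI edges are
#' stored once in canonical (lexicographically sorted) endpoint order.
#'
#' @param nodes data.frame with columns `id` (character), `roles`
#'   (comma-joined tokens from MIRNA, TF, TCOF, TARGET), and
#'   `disease_associated` (logical).
#' @param edges data.frame with columns `source`, `target`, `type`
#'   (TARGETING, REGULATION or PPI).
#' @param promoter_window promoter window length in nt the network was built
#'   for (e.g. 1000 or 5000); `NA` if unknown.
#' @param validate check all structural invariants (role vocabulary, edge
#'   endpoint roles, duplicate edges)? Disable only for trusted input.
#' @return An object of class `ocm_network`: a list with elements `nodes`,
#'   `edges` and `promoter_window`.
#' @seealso [build_network()], [census()]
#' @export
new_network <- function(nodes, edges, promoter_window = NA_integer_,
                        validate = TRUE) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  nodes <- data.frame(
    id = as.character(nodes$id),
    roles = as.character(nodes$roles),
    disease_associated = as.logical(nodes$disease_associated),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    source = as.character(edges$source),
    target = as.character(edges$target),
    type = as.character(edges$type),
    stringsAsFactors = FALSE
  )
  # canonical storage order for undirected edges
  ppi <- edges$type == "PPI"
  flip <- ppi & edges$source > edges$target
  if (any(flip)) {
    tmp <- edges$source[flip]
    edges$source[flip] <- edges$target[flip]
    edges$target[flip] <- tmp
  }
  edges <- unique(edges)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- edges[order(match(edges$type, EDGE_TYPES), edges$source,
                       edges$target), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  net <- structure(
    list(nodes = nodes, edges = edges,
         promoter_window = as.integer(promoter_window)),
    class = "ocm_network"
  )
  if (validate) validate_network(net)
  net
}

#' Validate the structural invariants of a network
#'
#' Checks that every node has a non-empty set of known roles, that the MIRNA
#' role never co-occurs with a protein role, that the TARGET role implies
#' disease association, that every edge endpoint exists and carries the role
#' its edge type requires, and that no (source, target, type) triple is
#' duplicated.
#'
#' @param network an `ocm_network`.
#' @return `network`, invisibly; errors describe the first violation found.
#' @export
validate_network <- function(network) {
  stopifnot(inherits(network, "ocm_network"))
  nodes <- network$nodes
  edges <- network$edges
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node id: ", nodes$id[duplicated(nodes$id)][1])
  }
  rl <- split_roles(nodes$roles)
  bad <- lengths(rl) == 0L | !vapply(rl, function(r) all(r %in% NODE_ROLES),
                                     TRUE)
  if (any(bad)) stop("node with empty or unknown roles: ", nodes$id[bad][1])
  mixed <- vapply(rl, function(r) "MIRNA" %in% r && length(r) > 1L, TRUE)
  if (any(mixed)) {
    stop("miRNA/protein namespace collision on node: ", nodes$id[mixed][1])
  }
  is_target <- vapply(rl, function(r) "TARGET" %in% r, TRUE)
  if (any(is_target & !nodes$disease_associated)) {
    stop("TARGET node not flagged disease-associated: ",
         nodes$id[is_target & !nodes$disease_associated][1])
  }
  if (nrow(edges)) {
    if (!all(edges$type %in% EDGE_TYPES)) {
      stop("unknown edge type: ", setdiff(edges$type, EDGE_TYPES)[1])
    }
    missing <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(missing)) stop("edge endpoint not in node set: ", missing[1])
    role_of <- setNames(rl, nodes$id)
    has <- function(ids, role) {
      vapply(role_of[ids], function(r) role %in% r, TRUE)
    }
    protein <- function(ids) {
      vapply(role_of[ids], function(r) any(r %in% PROTEIN_ROLES), TRUE)
    }
    tg <- edges[edges$type == "TARGETING", ]
    if (nrow(tg) && !all(has(tg$source, "MIRNA") & has(tg$target, "TARGET"))) {
      stop("TARGETING edge must run miRNA -> TARGET")
    }
    rg <- edges[edges$type == "REGULATION", ]
    if (nrow(rg) && !all(has(rg$source, "TF") & has(rg$target, "MIRNA"))) {
      stop("REGULATION edge must run TF -> miRNA")
    }
    pp <- edges[edges$type == "PPI", ]
    if (nrow(pp)) {
      if (!all(protein(pp$source) & protein(pp$target))) {
        stop("PPI edge endpoints must both be proteins")
      }
      if (any(pp$source > pp$target)) {
        stop("PPI edge stored out of canonical endpoint order")
      }
    }
    if (anyDuplicated(edges)) stop("duplicate (source, target, type) edge")
  }
  invisible(network)
}

#' @export
print.ocm_network <- function(x, ...) {
  cts <- census(x)
  cat(sprintf(
    "<ocm_network> promoter window: %s nt\n  %d nodes (%d miRNAs, %d targets, %d TFs, %d TcoFs)\n  %d edges (%d targeting, %d regulation, %d PPI)\n",
    ifelse(is.na(x$promoter_window), "?", x$promoter_window),
    cts$total_nodes, cts$n_mirnas, cts$n_targets, cts$n_tfs, cts$n_tcofs,
    cts$total_edges, cts$n_edges_targeting, cts$n_edges_regulation,
    cts$n_edges_ppi))
  invisible(x)
}

node_has_role <- function(network, role) {
  vapply(split_roles(network$nodes$roles), function(r) role %in% r, TRUE)
}

roles_of <- function(network, id) {
  i <- match(id, network$nodes$id)
  if (is.na(i)) stop("unknown node id: ", id)
  split_roles(network$nodes$roles[i])[[1]]
}

#' Build a disease-centred regulatory network from association tables
#'
#' Applies the retention cascade: miRNAs are kept iff they have at least one
#' verified target in the disease gene list; those disease targets are kept;
#' TFs are kept iff they have at least one binding-site hit in a retained
#' miRNA's promoter (the hit table must already be filtered to the requested
#' promoter window and score threshold, see [filter_tfbs_hits()]); TcoFs are
#' kept iff flagged high-confidence and interacting with a retained TF.
#' Protein-protein interactions are restricted to pairs whose both endpoints
#' are already retained — no new partner proteins are introduced. TcoF-TF
#' interactions enter as PPI-type edges; multiple binding-site hits of one TF
#' in one promoter collapse to a single REGULATION edge.
#'
#' A protein identifier appearing in several tables yields a single node
#' carrying the union of roles (e.g. a TF that is itself a disease target).
#' miRNA and protein identifiers must not collide.
#'
#' @param mirna_targets data.frame with columns `mirna_id`, `target_id`:
#'   experimentally verified miRNA -> gene pairs.
#' @param disease_genes character vector (or data.frame with column
#'   `gene_id`) of disease-associated gene identifiers.
#' @param tf_hits data.frame with columns `tf_id`, `mirna_id` (additional
#'   columns such as scores are ignored here), already score- and
#'   window-filtered.
#' @param tcof_pairs data.frame with columns `tcof_id`, `tf_id` and
#'   optionally `confidence` (rows other than `"high"` are dropped; absent
#'   column means all rows are high-confidence).
#' @param ppi_pairs data.frame with columns `protein_a`, `protein_b`.
#' @param promoter_window promoter window length in nt recorded on the
#'   network (metadata only; filtering happens upstream).
#' @return An `ocm_network`.
#' @examples
#' net <- build_network(
#'   mirna_targets = data.frame(mirna_id = "miR-1", target_id = "G1"),
#'   disease_genes = "G1",
#'   tf_hits = data.frame(tf_id = "TFA", mirna_id = "miR-1"),
#'   tcof_pairs = data.frame(tcof_id = "COF1", tf_id = "TFA",
#'                           confidence = "high"),
#'   ppi_pairs = data.frame(protein_a = "G1", protein_b = "TFA"),
#'   promoter_window = 1000)
#' census(net)
#' @export
build_network <- function(mirna_targets, disease_genes, tf_hits, tcof_pairs,
                          ppi_pairs, promoter_window = NA_integer_) {
  if (is.data.frame(disease_genes)) disease_genes <- disease_genes$gene_id
  disease_genes <- unique(as.character(disease_genes))
  mirna_targets <- unique(mirna_targets[c("mirna_id", "target_id")])

  mirna_universe <- unique(as.character(mirna_targets$mirna_id))
  if (nrow(tf_hits)) {
    unknown <- setdiff(unique(as.character(tf_hits$mirna_id)), mirna_universe)
    if (length(unknown)) {
      stop("tf_hits references unknown miRNA id: ", unknown[1])
    }
  }
  protein_ids <- unique(c(
    as.character(mirna_targets$target_id), disease_genes,
    if (nrow(tf_hits)) as.character(tf_hits$tf_id),
    if (nrow(tcof_pairs)) c(as.character(tcof_pairs$tcof_id),
                            as.character(tcof_pairs$tf_id)),
    if (nrow(ppi_pairs)) c(as.character(ppi_pairs$protein_a),
                           as.character(ppi_pairs$protein_b))))
  clash <- intersect(mirna_universe, protein_ids)
  if (length(clash)) {
    stop("identifier used as both miRNA and protein: ", clash[1])
  }

  # (1) miRNAs with >= 1 disease-associated verified target, (2) the targets
  keep <- mirna_targets$target_id %in% disease_genes
  targeting <- mirna_targets[keep, , drop = FALSE]
  mirnas <- unique(targeting$mirna_id)
  if (!length(mirnas)) {
    stop("no miRNA has a verified target in the disease gene list; ",
         "nothing to analyse")
  }
  targets <- unique(targeting$target_id)

  # (3) TFs hitting a retained miRNA promoter; multi-hits collapse
  regulation <- unique(tf_hits[tf_hits$mirna_id %in% mirnas,
                               c("tf_id", "mirna_id"), drop = FALSE])
  tfs <- unique(as.character(regulation$tf_id))

  # (4) high-confidence TcoFs of retained TFs
  if (nrow(tcof_pairs) && "confidence" %in% names(tcof_pairs)) {
    tcof_pairs <- tcof_pairs[tcof_pairs$confidence == "high", , drop = FALSE]
  }
  tcof_links <- unique(tcof_pairs[tcof_pairs$tf_id %in% tfs,
                                  c("tcof_id", "tf_id"), drop = FALSE])
  tcofs <- unique(as.character(tcof_links$tcof_id))

  proteins <- unique(c(targets, tfs, tcofs))

  # (6) PPIs induced on the retained protein set; TcoF links enter as PPI
  ppi <- ppi_pairs[ppi_pairs$protein_a %in% proteins &
                     ppi_pairs$protein_b %in% proteins, , drop = FALSE]
  ppi_edges <- rbind(
    data.frame(source = as.character(ppi$protein_a),
               target = as.character(ppi$protein_b),
               stringsAsFactors = FALSE),
    data.frame(source = as.character(tcof_links$tcof_id),
               target = as.character(tcof_links$tf_id),
               stringsAsFactors = FALSE))

  typed <- function(src, tgt, type) {
    data.frame(source = as.character(src), target = as.character(tgt),
               type = rep(type, length(src)), stringsAsFactors = FALSE)
  }
  edges <- rbind(
    typed(targeting$mirna_id, targeting$target_id, "TARGETING"),
    typed(regulation$tf_id, regulation$mirna_id, "REGULATION"),
    typed(ppi_edges$source, ppi_edges$target, "PPI"))

  ids <- c(mirnas, proteins)
  role_list <- c(
    rep(list("MIRNA"), length(mirnas)),
    lapply(proteins, function(p) {
      c(if (p %in% targets) "TARGET", if (p %in% tfs) "TF",
        if (p %in% tcofs) "TCOF")
    }))
  nodes <- data.frame(
    id = ids,
    roles = join_roles(role_list),
    disease_associated = ids %in% disease_genes,
    stringsAsFactors = FALSE)

  new_network(nodes, edges, promoter_window)
}

#' Census of node roles and edge types
#'
#' Counts nodes once per role they carry (so role counts may sum to more than
#' the number of distinct nodes), edges by type, and totals.
#'
#' @param network an `ocm_network`.
#' @return A list of class `ocm_census` with elements `n_mirnas`,
#'   `n_targets`, `n_tfs`, `n_tcofs`, `n_edges_targeting`,
#'   `n_edges_regulation`, `n_edges_ppi`, `total_nodes`, `total_edges` and
#'   `promoter_window`.
#' @export
census <- function(network) {
  stopifnot(inherits(network, "ocm_network"))
  structure(list(
    n_mirnas = sum(node_has_role(network, "MIRNA")),
    n_targets = sum(node_has_role(network, "TARGET")),
    n_tfs = sum(node_has_role(network, "TF")),
    n_tcofs = sum(node_has_role(network, "TCOF")),
    n_edges_targeting = sum(network$edges$type == "TARGETING"),
    n_edges_regulation = sum(network$edges$type == "REGULATION"),
    n_edges_ppi = sum(network$edges$type == "PPI"),
    total_nodes = nrow(network$nodes),
    total_edges = nrow(network$edges),
    promoter_window = network$promoter_window
  ), class = "ocm_census")
}

#' @export
print.ocm_census <- function(x, ...) {
  cat(sprintf(
    paste0("Network census (window %s nt)\n",
           "  miRNAs %d | targets %d | TFs %d | TcoFs %d\n",
           "  edges: targeting %d, regulation %d, PPI %d\n",
           "  total: %d nodes, %d edges\n"),
    ifelse(is.na(x$promoter_window), "?", x$promoter_window),
    x$n_mirnas, x$n_targets, x$n_tfs, x$n_tcofs,
    x$n_edges_targeting, x$n_edges_regulation, x$n_edges_ppi,
    x$total_nodes, x$total_edges))
  invisible(x)
}

#' @export
as.data.frame.ocm_census <- function(x, ...) {
  data.frame(lapply(unclass(x), function(v) if (is.null(v)) NA else v))
}

#' miRNAs regulated by a transcription factor
#'
#' @param network an `ocm_network`.
#' @param tf node identifier carrying the TF role.
#' @return Sorted character vector of miRNA identifiers with a REGULATION
#'   edge from `tf`.
#' @export
tf_regulon <- function(network, tf) {
  if (!"TF" %in% roles_of(network, tf)) stop("node is not a TF: ", tf)
  e <- network$edges
  sort(unique(e$target[e$type == "REGULATION" & e$source == tf]))
}

#' Proteins reached downstream of a TF through its regulated miRNAs
#'
#' Union of the targets of all miRNAs in the TF's regulon.
#'
#' @inheritParams tf_regulon
#' @return Sorted character vector of protein identifiers.
#' @export
tf_downstream_targets <- function(network, tf) {
  mirnas <- tf_regulon(network, tf)
  e <- network$edges
  sort(unique(e$target[e$type == "TARGETING" & e$source %in% mirnas]))
}

#' Number of distinct miRNAs targeting a protein
#'
#' @param network an `ocm_network`.
#' @param protein protein node identifier.
#' @return Integer count of distinct miRNAs with a TARGETING edge into
#'   `protein` (0 for an untargeted protein).
#' @export
mirna_in_degree <- function(network, protein) {
  r <- roles_of(network, protein)
  if ("MIRNA" %in% r) stop("node is a miRNA, not a protein: ", protein)
  e <- network$edges
  length(unique(e$source[e$type == "TARGETING" & e$target == protein]))
}
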