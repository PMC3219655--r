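# Readers and writers for the association-table TSV dialect.
#
# Dialect: literal tab separators, UTF-8, Unix newlines, mandatory header
# row, '#'-prefixed comment lines and blank lines skipped. Third-party
# layouts are adapted through a column-mapping (canonical name -> file
# column name), optionally loaded from a YAML or JSON file.

#' Canonical input-table schemas
#'
#' Column names and types expected for each of the five association tables
#' (character by default).
#'
#' @return Named list of schemas; each schema is a named character vector
#'   mapping column name to type (`"character"`, `"numeric"` or
#'   `"integer"`).
#' @export
oc_schemas <- function() {
  list(
    mirna_targets = c(mirna_id = "character", target_id = "character"),
    disease_genes = c(gene_id = "character"),
    tf_hits = c(tf_id = "character", mirna_id = "character",
                core_score = "numeric", matrix_score = "numeric",
                window_nt = "integer"),
    tcof_pairs = c(tcof_id = "character", tf_id = "character",
                   confidence = "character"),
    ppi_pairs = c(protein_a = "character", protein_b = "character")
  )
}

#' Read a headered TSV association table
#'
#' Reads the package's TSV dialect: tab-separated, header row mandatory,
#' blank lines and lines starting with `#` skipped. Columns are selected and
#' renamed through an optional column mapping and coerced to the schema
#' types; a coercion failure reports the offending (1-based, physical) line
#' number.
#'
#' @param path file path.
#' @param schema either the name of a canonical schema (see [oc_schemas()])
#'   or a named character vector of `column = type` pairs.
#' @param column_map optional named character vector mapping canonical column
#'   names to the column names used in the file, or a path to a YAML/JSON
#'   file holding such a mapping.
#' @return data.frame with the schema's columns, typed.
#' @export
read_assoc_table <- function(path, schema, column_map = NULL) {
  if (is.character(schema) && length(schema) == 1L &&
      schema %in% names(oc_schemas())) {
    schema <- oc_schemas()[[schema]]
  }
  stopifnot(is.character(schema), !is.null(names(schema)))
  if (!file.exists(path)) stop("file not found: ", path)
  column_map <- load_column_map(column_map)

  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*$", lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no header row in ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  body <- cells[-1]
  body_lineno <- lineno[-1]

  file_cols <- names(schema)
  if (!is.null(column_map)) {
    idx <- match(names(schema), names(column_map))
    file_cols <- ifelse(is.na(idx), names(schema), column_map[idx])
  }
  missing <- setdiff(file_cols, header)
  if (length(missing)) {
    stop("missing column '", missing[1], "' in ", path)
  }
  col_idx <- match(file_cols, header)

  out <- vector("list", length(schema))
  names(out) <- names(schema)
  raw <- lapply(seq_along(schema), function(j) {
    vapply(body, function(r) {
      if (length(r) < col_idx[j]) NA_character_ else r[[col_idx[j]]]
    }, "")
  })
  for (j in seq_along(schema)) {
    v <- raw[[j]]
    type <- schema[[j]]
    if (type == "character") {
      out[[j]] <- v
    } else {
      cv <- suppressWarnings(
        if (type == "integer") as.integer(v) else as.numeric(v))
      bad <- which(is.na(cv) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("cannot coerce '%s' to %s in column '%s' (%s line %d)",
                     v[bad[1]], type, names(schema)[j], path,
                     body_lineno[bad[1]]))
      }
      out[[j]] <- cv
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

load_column_map <- function(column_map) {
  if (is.null(column_map) || is.character(column_map) &&
      !is.null(names(column_map))) {
    return(column_map)
  }
  if (is.character(column_map) && length(column_map) == 1L) {
    if (grepl("\\.ya?ml$", column_map)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("the 'yaml' package is required to read YAML column maps")
      }
      return(unlist(yaml::read_yaml(column_map)))
    }
    return(unlist(jsonlite::read_json(column_map, simplifyVector = TRUE)))
  }
  if (is.list(column_map)) return(unlist(column_map))
  stop("column_map must be a named character vector, list, or file path")
}

#' Filter TF binding-site hits by score and promoter window
#'
#' Retains hits whose core and matrix scores are both at or above the
#' thresholds (boundary inclusive) and, when `window_nt` is given, whose
#' window matches. Retention is row-wise and order-preserving, hence
#' idempotent and commuting with table concatenation.
#'
#' @param hits data.frame with columns `core_score`, `matrix_score` and
#'   (if window filtering is requested) `window_nt`.
#' @param min_core,min_matrix minimum scores, default 0.9 each.
#' @param window_nt promoter window to retain (e.g. 1000 or 5000); `NULL`
#'   keeps all windows.
#' @return The retained rows of `hits`.
#' @export
filter_tfbs_hits <- function(hits, min_core = 0.9, min_matrix = 0.9,
                             window_nt = NULL) {
  if (!nrow(hits)) return(hits)
  sc <- c(hits$core_score, hits$matrix_score)
  if (any(is.na(sc)) || any(sc < 0) || any(sc > 1)) {
    stop("TFBS scores must lie in [0, 1]")
  }
  keep <- hits$core_score >= min_core & hits$matrix_score >= min_matrix
  if (!is.null(window_nt)) keep <- keep & hits$window_nt == window_nt
  hits[keep, , drop = FALSE]
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
}

#' Serialise a network to a node table and an edge table
#'
#' Writes two TSVs: a nodes file (`id`, `roles` as comma-joined sorted
#' tokens, `disease_associated` as 0/1) and an edges file (`source`,
#' `target`, `edge_type`). Reading them back with [read_network()]
#' reconstructs an identical network.
#'
#' @param network an `ocm_network`.
#' @param nodes_path,edges_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_network <- function(network, nodes_path, edges_path) {
  stopifnot(inherits(network, "ocm_network"))
  nd <- network$nodes
  nd$disease_associated <- as.integer(nd$disease_associated)
  write_tsv(nd, nodes_path)
  ed <- network$edges
  names(ed) <- c("source", "target", "edge_type")
  write_tsv(ed, edges_path)
  invisible(c(nodes = nodes_path, edges = edges_path))
}

#' Read a network from node and edge tables
#'
#' Reads the two-file layout written by [write_network()]. Third-party
#' layouts (differently named or ordered columns, other role separators or
#' edge-type labels) are adapted through `node_map`/`edge_map` column
#' mappings and the `role_sep`/`type_map` value translations, so published
#' supplementary network files can be parsed without editing them.
#'
#' @param nodes_path,edges_path input file paths.
#' @param node_map,edge_map optional column mappings (canonical name -> file
#'   column name) for the node file (`id`, `roles`, `disease_associated`)
#'   and edge file (`source`, `target`, `edge_type`).
#' @param role_sep separator between role tokens in the node file
#'   (default `","`).
#' @param role_map optional named character vector translating file role
#'   tokens to MIRNA/TF/TCOF/TARGET.
#' @param type_map optional named character vector translating file edge-type
#'   tokens to TARGETING/REGULATION/PPI.
#' @param promoter_window window length recorded on the returned network.
#' @param validate check network invariants after reading.
#' @return An `ocm_network`.
#' @export
read_network <- function(nodes_path, edges_path, node_map = NULL,
                         edge_map = NULL, role_sep = ",", role_map = NULL,
                         type_map = NULL, promoter_window = NA_integer_,
                         validate = TRUE) {
  nd <- read_assoc_table(nodes_path,
                         c(id = "character", roles = "character",
                           disease_associated = "character"),
                         column_map = node_map)
  ed <- read_assoc_table(edges_path,
                         c(source = "character", target = "character",
                           edge_type = "character"),
                         column_map = edge_map)
  roles <- strsplit(nd$roles, role_sep, fixed = TRUE)
  if (!is.null(role_map)) {
    roles <- lapply(roles, function(r) unname(role_map[r]))
  }
  nd$roles <- join_roles(roles)
  nd$disease_associated <- nd$disease_associated %in% c("1", "TRUE", "true")
  if (!is.null(type_map)) ed$edge_type <- unname(type_map[ed$edge_type])
  new_network(
    nodes = nd,
    edges = data.frame(source = ed$source, target = ed$target,
                       type = ed$edge_type, stringsAsFactors = FALSE),
    promoter_window = promoter_window, validate = validate)
}
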