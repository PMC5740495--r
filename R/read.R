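# Readers and writers for the external table formats: MaxQuant-style
# proteinGroups tables, study designs, STRING-style edge lists and
# biotinylation-site tables. All are plain TSV.

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  na = c("", "NA", "NaN"), ...)
}

plus_flag <- function(x) {
  if (is.null(x)) return(FALSE)
  !is.na(x) & x == "+"
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Parses a tab-separated protein-group quantification table in the
#' MaxQuant `proteinGroups.txt` dialect: one row per protein group, per-run
#' intensity columns sharing a common prefix (`"Intensity <run>"`), optional
#' `"iBAQ <run>"` columns, unique-peptide counts and `+`-encoded reverse /
#' contaminant flags. Reverse and contaminant rows are dropped, intensity
#' zeros are converted to missing, and iBAQ columns are kept as a side table
#' in the `ibaq` attribute.
#'
#' @param path path to the TSV file.
#' @param intensity_prefix prefix of per-run intensity columns
#'   (default `"Intensity"`).
#' @param design optional study design (see [read_design()]); when given,
#'   every designed run must have an intensity column, otherwise a format
#'   error lists the missing runs.
#' @return A raw-scale [intensity_matrix()] with attribute `ibaq` (tibble of
#'   per-run iBAQ values, or `NULL`).
#' @export
read_protein_groups <- function(path, intensity_prefix = "Intensity",
                                design = NULL) {
  tab <- read_tsv_quiet(path)
  if (!ncol(tab)) stop_format("empty protein-group table: %s", path)

  pat <- paste0("^", intensity_prefix, " ")
  int_cols <- grep(pat, names(tab), value = TRUE)
  if (!length(int_cols)) {
    stop_format("no per-run intensity columns with prefix '%s ' found in %s",
                intensity_prefix, path)
  }
  run_ids <- sub(pat, "", int_cols)
  if (!is.null(design)) {
    missing_runs <- setdiff(design$run_id, run_ids)
    if (length(missing_runs)) {
      stop_format("intensity columns absent for designed runs: %s",
                  paste(missing_runs, collapse = ", "))
    }
  }

  id_col <- intersect(c("Majority protein IDs", "Protein IDs", "group_id"),
                      names(tab))[1]
  if (is.na(id_col)) stop_format("no protein group id column found in %s", path)
  ids <- as.character(tab[[id_col]])
  if (anyDuplicated(ids)) {
    stop_format("duplicate protein group ids: %s",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }

  proteins <- tibble(
    group_id = ids,
    gene_name = if ("Gene names" %in% names(tab)) {
      stringr::str_split_i(as.character(tab[["Gene names"]]), ";", 1)
    } else ids,
    unique_peptides = if ("Unique peptides" %in% names(tab)) {
      as.integer(tab[["Unique peptides"]])
    } else NA_integer_,
    is_reverse = plus_flag(tab[["Reverse"]]),
    is_contaminant = plus_flag(tab[["Potential contaminant"]])
  )

  vals <- as.matrix(tab[int_cols])
  mode(vals) <- "numeric"
  colnames(vals) <- run_ids
  vals[!is.na(vals) & vals == 0] <- NA_real_

  ibaq_cols <- grep("^iBAQ ", names(tab), value = TRUE)
  ibaq <- NULL
  if (length(ibaq_cols)) {
    ibaq <- as_tibble(tab[ibaq_cols])
    names(ibaq) <- sub("^iBAQ ", "", names(ibaq))
    ibaq <- dplyr::bind_cols(tibble(group_id = ids), ibaq)
  }

  keep <- !proteins$is_reverse & !proteins$is_contaminant
  m <- intensity_matrix(vals[keep, , drop = FALSE], proteins[keep, ], scale = "raw")
  if (!is.null(ibaq)) attr(m, "ibaq") <- ibaq[keep, ]
  m
}

DESIGN_COLS <- c("run_id", "cell_line", "bait", "terminus",
                 "bio_rep", "tech_rep", "is_control")

#' Validate a study-design tibble
#'
#' Checks the column set, the terminus vocabulary (`N`, `C`, `none`) and
#' uniqueness of `(cell_line, bio_rep, tech_rep)`.
#'
#' @param design tibble with the columns documented in [read_design()].
#' @return The validated design (invisibly coerced types).
#' @export
validate_design <- function(design) {
  missing_cols <- setdiff(DESIGN_COLS, names(design))
  if (length(missing_cols)) {
    stop_design("design table lacks required columns: %s",
                paste(missing_cols, collapse = ", "))
  }
  if (!nrow(design)) stop_design("design table is empty")
  design <- mutate(as_tibble(design),
                   run_id = as.character(.data$run_id),
                   cell_line = as.character(.data$cell_line),
                   bait = as.character(.data$bait),
                   terminus = as.character(.data$terminus),
                   bio_rep = as.integer(.data$bio_rep),
                   tech_rep = as.integer(.data$tech_rep),
                   is_control = as.logical(.data$is_control))
  bad_term <- setdiff(unique(design$terminus), c("N", "C", "none"))
  if (length(bad_term)) {
    stop_design("unknown terminus token(s): %s", paste(bad_term, collapse = ", "))
  }
  key <- paste(design$cell_line, design$bio_rep, design$tech_rep)
  if (anyDuplicated(key)) {
    stop_design("duplicate (cell_line, bio_rep, tech_rep): %s",
                paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  if (anyDuplicated(design$run_id)) stop_design("duplicate run ids in design")
  if (any(design$bio_rep < 1L) || any(design$tech_rep < 1L)) {
    stop_design("bio_rep and tech_rep must be >= 1")
  }
  design
}

#' Read a study-design table
#'
#' The design maps every MS run to its cell line, bait, BirA* fusion
#' terminus, biological and technical replicate, and control status.
#' Required tab-separated columns: `run_id`, `cell_line`, `bait`,
#' `terminus` (`N`/`C`/`none`), `bio_rep`, `tech_rep`, `is_control`.
#'
#' @param path path to the TSV file.
#' @return A validated design tibble.
#' @export
read_design <- function(path) {
  tab <- tryCatch(read_tsv_quiet(path),
                  error = function(e) stop_design("cannot read design: %s",
                                                  conditionMessage(e)))
  validate_design(tab)
}

#' Read a weighted protein-protein interaction edge list
#'
#' Whitespace- or tab-separated columns: node a, node b, combined score.
#' Scores on a 0-1000 scale (as STRING distributes them) are detected by
#' any weight exceeding 1 and divided by 1000. Edges with normalized weight
#' strictly greater than `threshold` are retained; self-loops are dropped
#' with a warning; duplicate undirected pairs keep their maximum weight.
#'
#' @param path path to the edge-list file.
#' @param threshold minimum combined score on the normalized 0-1 scale
#'   (strict inequality; default 0.7).
#' @param nodes optional character vector (or path to a one-column file) of
#'   node ids to retain even when isolated.
#' @return A `ppi_network`: tibble of edges (`from`, `to`, `weight`) with a
#'   `nodes` attribute holding all node ids.
#' @export
read_network <- function(path, threshold = 0.7, nodes = NULL) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop_format("edge list needs columns: node, node, weight")
  if (is.character(tab[[1]]) && tab[1, 1] %in% c("from", "protein1", "node1")) {
    tab <- tab[-1, ]
    tab[[3]] <- as.numeric(tab[[3]])
  }
  edges <- tibble(from = as.character(tab[[1]]),
                  to = as.character(tab[[2]]),
                  weight = as.numeric(tab[[3]]))
  if (is.character(nodes) && length(nodes) == 1 && file.exists(nodes)) {
    nodes <- utils::read.table(nodes, header = FALSE)[[1]]
  }
  as_ppi_network(edges, threshold = threshold, extra_nodes = nodes)
}

#' Build a validated network from an edge tibble
#'
#' @param edges tibble with columns `from`, `to`, `weight`.
#' @param threshold retain edges with normalized weight strictly above this.
#' @param extra_nodes node ids kept even if they touch no retained edge.
#' @return A `ppi_network` edge tibble (see [read_network()]).
#' @export
as_ppi_network <- function(edges, threshold = 0.7, extra_nodes = NULL) {
  if (any(edges$weight < 0)) stop_format("negative edge weights are not allowed")
  if (any(edges$weight > 1)) edges$weight <- edges$weight / 1000
  if (any(edges$weight > 1)) stop_format("edge weights above 1000 are not a known scale")

  loops <- edges$from == edges$to
  if (any(loops)) {
    rlang::warn(sprintf("dropping %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, ]
  }
  # canonical undirected orientation, deduplicate keeping the max weight
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  edges <- tibble(from = a, to = b, weight = edges$weight)
  edges <- edges |>
    group_by(.data$from, .data$to) |>
    summarise(weight = max(.data$weight), .groups = "drop")
  edges <- filter(edges, .data$weight > threshold)
  edges <- arrange(edges, .data$from, .data$to)

  node_ids <- sort(unique(c(edges$from, edges$to, as.character(extra_nodes))))
  structure(edges, class = c("ppi_network", class(edges)),
            nodes = node_ids, threshold = threshold)
}

#' Node ids of a network
#' @param net a `ppi_network`.
#' @return Character vector of node identifiers.
#' @export
network_nodes <- function(net) attr(net, "nodes")

#' Convert a `ppi_network` to an igraph object
#' @param net a `ppi_network`.
#' @return An undirected weighted `igraph` graph over all nodes.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(as.data.frame(net)[c("from", "to", "weight")],
                                     directed = FALSE,
                                     vertices = network_nodes(net))
  igraph::set_edge_attr(g, "weight", value = net$weight)
}

#' Read a biotinylation-site intensity table
#'
#' Tab-separated columns: `protein`, `position` (1-based residue index) and
#' one intensity column per run. Duplicate (protein, position) rows are
#' summed per run with a warning; zeros become missing.
#'
#' @param path path to the TSV file.
#' @param protein_lengths optional named vector of protein lengths; sites
#'   beyond the length trigger a validation warning.
#' @return A site-level [intensity_matrix()] (`sites` field populated,
#'   rows keyed `protein@position`).
#' @export
read_site_table <- function(path, protein_lengths = NULL) {
  tab <- read_tsv_quiet(path)
  need <- c("protein", "position")
  if (!all(need %in% names(tab))) {
    stop_format("site table needs columns 'protein' and 'position'")
  }
  if (any(tab$position < 1)) stop_format("site positions must be >= 1")
  run_cols <- setdiff(names(tab), need)
  if (!length(run_cols)) stop_format("site table has no per-run intensity columns")

  key <- paste0(tab$protein, "@", tab$position)
  if (anyDuplicated(key)) {
    rlang::warn("duplicate (protein, position) rows: intensities summed per run")
    tab <- tab |>
      group_by(.data$protein, .data$position) |>
      summarise(across(dplyr::all_of(run_cols), \(x) sum(x, na.rm = TRUE)),
                .groups = "drop")
  }
  tab <- arrange(tab, .data$protein, .data$position)
  if (!is.null(protein_lengths)) {
    len <- protein_lengths[tab$protein]
    over <- !is.na(len) & tab$position > len
    if (any(over)) {
      rlang::warn(sprintf("%d site(s) beyond the supplied protein length", sum(over)))
    }
  }
  vals <- as.matrix(tab[setdiff(names(tab), need)])
  mode(vals) <- "numeric"
  vals[!is.na(vals) & vals == 0] <- NA_real_
  sites <- tibble(protein = as.character(tab$protein),
                  position = as.integer(tab$position))
  proteins <- tibble(group_id = paste0(sites$protein, "@", sites$position))
  intensity_matrix(vals, proteins, scale = "raw", sites = sites)
}

#' Write an intensity matrix (and mask) to TSV
#'
#' Values are written with full precision; missing cells are empty. The
#' companion [read_intensity_matrix()] restores values, mask and metadata.
#'
#' @param m an `intensity_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_intensity_matrix <- function(m, path) {
  tab <- dplyr::bind_cols(m$proteins, as_tibble(m$values))
  attrs <- sprintf("# scale=%s", m$scale)
  readr::write_lines(attrs, path)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read back a matrix written by [write_intensity_matrix()]
#' @param path TSV path produced by [write_intensity_matrix()].
#' @return The restored `intensity_matrix`.
#' @export
read_intensity_matrix <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  scale <- sub("^# scale=", "", first)
  tab <- read_tsv_quiet(path, skip = 1)
  meta_cols <- intersect(c("group_id", "gene_name", "unique_peptides",
                           "is_reverse", "is_contaminant"), names(tab))
  vals <- as.matrix(tab[setdiff(names(tab), meta_cols)])
  mode(vals) <- "numeric"
  intensity_matrix(vals, tab[meta_cols], scale = scale)
}
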