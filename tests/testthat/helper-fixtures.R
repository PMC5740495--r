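# Shared fixture builders. Everything is generated in code at test time.

# A small simulation configuration; override any argument.
tiny_config <- function(...) {
  defaults <- list(n_proteins = 200, n_ntrs = 4, n_controls = 2,
                   n_bio = 4, n_tech = 2, n_complexes = 2, complex_size = 4,
                   site_proteins = 20)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Write a MaxQuant-dialect proteinGroups fixture and return its path.
write_pg_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                             reverse_row = TRUE) {
  tab <- data.frame(
    check.names = FALSE,
    `Majority protein IDs` = c("P1", "P2", "REV__P3"),
    `Gene names` = c("GENE1;ALT1", "GENE2", "GENE3"),
    `Unique peptides` = c(5L, 2L, 3L),
    Reverse = c("", "", if (reverse_row) "+" else ""),
    `Potential contaminant` = c("", "", ""),
    `Intensity run1` = c(1e6, 0, 2e5),
    `Intensity run2` = c(2e6, 3e5, 2e5),
    `Intensity run3` = c(1.5e6, 4e5, 2e5),
    `Intensity run4` = c(1e6, 5e5, 2e5),
    `iBAQ run1` = c(1e4, 0, 2e3),
    `iBAQ run2` = c(2e4, 3e3, 2e3),
    `iBAQ run3` = c(1.5e4, 4e3, 2e3),
    `iBAQ run4` = c(1e4, 5e3, 2e3)
  )
  path <- file.path(dir, "proteinGroups.txt")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Build an intensity_matrix directly from a numeric matrix.
make_matrix <- function(values, scale = "log2") {
  if (is.null(rownames(values))) rownames(values) <- paste0("P", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("r", seq_len(ncol(values)))
  intensity_matrix(values,
                   tibble::tibble(group_id = rownames(values),
                                  unique_peptides = 5L),
                   scale = scale)
}

# A minimal design for bare matrices: one line per column, or custom.
design_for <- function(cols, cell_line, bio_rep, bait = cell_line,
                       is_control = grepl("^CTRL", cell_line)) {
  proxiscore::validate_design(tibble::tibble(
    run_id = cols, cell_line = cell_line, bait = bait,
    terminus = ifelse(is_control, "none", "N"),
    bio_rep = bio_rep, tech_rep = 1L, is_control = is_control
  ))
}

# Brute-force closed-testing oracle: minimum Simes-adjusted elementary
# p-value over all 2^m - 1 intersection hypotheses.
closed_testing_min_p <- function(p) {
  m <- length(p)
  subsets <- unlist(lapply(seq_len(m), function(k) {
    utils::combn(seq_len(m), k, simplify = FALSE)
  }), recursive = FALSE)
  simes_of <- vapply(subsets, function(idx) simes_pvalue(p[idx]), numeric(1))
  adj <- vapply(seq_len(m), function(i) {
    max(simes_of[vapply(subsets, function(s) i %in% s, logical(1))])
  }, numeric(1))
  min(adj)
}
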