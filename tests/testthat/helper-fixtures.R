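# in-memory fixtures shared across test files

# a small UniProt mapping table: each symbol present in each species,
# one synonym and one cross-reference per entry
tiny_uniprot <- function(symbols = c("GENE1", "GENE2", "GENE3"),
                         species = c("hsa", "mmu", "dre")) {
  grid <- tidyr::expand_grid(gene_symbol = symbols, species = species)
  grid$accession <- sprintf("P%05d", seq_len(nrow(grid)))
  tibble::tibble(
    accession = grid$accession,
    gene_symbol = grid$gene_symbol,
    synonyms = paste0("SYN-", grid$gene_symbol),
    species = grid$species,
    protein_name = paste("Protein", grid$gene_symbol, grid$species),
    go_terms = paste0("GO:000000", seq_len(nrow(grid))),
    cross_references = paste0("XR-", grid$accession)
  )
}

# build a well-formed MTI record tibble (methods as list column)
make_records <- function(source_db, mirna_id, target_symbol, species,
                         methods = "qPCR", clip_support = 0L,
                         mirbase_acc = "") {
  n <- max(lengths(list(source_db, mirna_id, target_symbol, species)))
  tibble::tibble(
    source_db = rep_len(source_db, n),
    mirna_id = rep_len(mirna_id, n),
    mirbase_acc = rep_len(mirbase_acc, n),
    target_symbol = rep_len(target_symbol, n),
    species = rep_len(species, n),
    methods = rep_len(strsplit(rep_len(methods, n), ";"), n),
    clip_support = rep_len(as.integer(clip_support), n)
  )
}

# write an interchange TSV from a plain character data frame
write_db_file <- function(rows, path) {
  readr::write_tsv(rows, path)
  path
}

# randomized record fixture with a known composition for filter tests
random_records <- function(n = 200, seed = 1) {
  withr::with_seed(seed, {
    dbs <- sample(c("tarbase", "mirtarbase", "mirecords", "starbase"), n,
                  replace = TRUE)
    tibble::tibble(
      source_db = dbs,
      mirna_id = paste0(sample(c("hsa", "mmu", "dre"), n, replace = TRUE),
                        "-miR-", sample(1:40, n, replace = TRUE)),
      mirbase_acc = "",
      target_symbol = paste0("GENE", sample(1:30, n, replace = TRUE)),
      species = sample(c("hsa", "mmu", "dre"), n, replace = TRUE),
      methods = lapply(seq_len(n), function(i) {
        sample(c("Reporter assay", "Western blot", "qPCR", "NGS"),
               sample(1:2, 1))
      }),
      clip_support = ifelse(dbs == "starbase",
                            sample(1:5, n, replace = TRUE), 0L)
    )
  })
}
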