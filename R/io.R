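# Plain-text readers/writers for the pipeline's input bundle. All interval
# files use 0-based half-open coordinates (BED convention).

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, ...)
}

#' Write a synthetic dataset bundle to disk
#'
#' Emits every table of a [generate_dataset()] bundle in the formats the
#' pipeline reads: `cnes.bed` (BED4) plus `cnes_annotation.tsv`,
#' `evidence.tsv`, per-species `gaps/<species>.bed` and
#' `traces/<species>.bed`, `hits.tsv`, `tss.bed` (BED6 with the TSS as a
#' 1 bp feature), `orthologs.tsv`, `tree.nwk`, `roles.yaml` and
#' `truth.json`.
#'
#' @param ds a `cne_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "cne_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(ds$cnes[, c("chrom", "start", "end", "id")],
             file.path(dir, "cnes.bed"))
  .write_tsv(ds$cnes[, c("id", "length", "constraint_rs", "phylop_p",
                         "ancestry_pre_mammal")],
             file.path(dir, "cnes_annotation.tsv"))
  .write_tsv(ds$evidence, file.path(dir, "evidence.tsv"))
  .write_tsv(ds$hits, file.path(dir, "hits.tsv"))
  .write_tsv(ds$orthologs, file.path(dir, "orthologs.tsv"))
  tssbed <- data.frame(chrom = ds$tss$chrom, start = ds$tss$pos,
                       end = ds$tss$pos + 1L, name = ds$tss$gene,
                       score = 0L, strand = ds$tss$strand)
  .write_tsv(tssbed, file.path(dir, "tss.bed"))
  for (sub in c("gaps", "traces")) {
    d <- ds[[sub]]
    dir.create(file.path(dir, sub), showWarnings = FALSE)
    for (s in unique(d$species))
      .write_tsv(d[d$species == s, c("scaffold", "start", "end")],
                 file.path(dir, sub, paste0(s, ".bed")))
  }
  writeLines(ds$config$tree$newick, file.path(dir, "tree.nwk"))
  roles <- ds$config$tree$roles
  yaml_lines <- unlist(lapply(names(roles), function(r)
    c(paste0(r, ":"), paste0("  - ", roles[[r]]))))
  writeLines(yaml_lines, file.path(dir, "roles.yaml"))
  truth <- list(
    events_by_cne = ds$truth$events_by_cne,
    per_branch = as.list(ds$truth$per_branch),
    propensity = as.list(ds$truth$propensity),
    seed = ds$config$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset bundle written by [write_dataset()]
#'
#' @param dir directory containing the bundle.
#' @return list with `cnes`, `evidence`, `gaps`, `hits`, `traces`, `tss`,
#'   `orthologs`, `tree` (a `cne_phylo`).
#' @export
read_dataset <- function(dir) {
  roles <- .read_roles(file.path(dir, "roles.yaml"))
  tree <- parse_tree(paste(readLines(file.path(dir, "tree.nwk")),
                           collapse = ""), roles)
  bed <- .read_tsv(file.path(dir, "cnes.bed"))
  ann <- .read_tsv(file.path(dir, "cnes_annotation.tsv"))
  cnes <- cbind(bed[, c("id", "chrom", "start", "end")],
                ann[match(bed$id, ann$id),
                    setdiff(names(ann), "id"), drop = FALSE])
  rownames(cnes) <- NULL
  read_species_dir <- function(sub) {
    files <- list.files(file.path(dir, sub), pattern = "\\.bed$",
                        full.names = TRUE)
    if (!length(files))
      return(data.frame(species = character(0), scaffold = character(0),
                        start = numeric(0), end = numeric(0)))
    do.call(rbind, lapply(files, function(f)
      cbind(species = sub("\\.bed$", "", basename(f)), .read_tsv(f))))
  }
  tssbed <- .read_tsv(file.path(dir, "tss.bed"))
  list(cnes = cnes,
       evidence = .read_tsv(file.path(dir, "evidence.tsv")),
       gaps = read_species_dir("gaps"),
       hits = .read_tsv(file.path(dir, "hits.tsv")),
       traces = read_species_dir("traces"),
       tss = data.frame(chrom = tssbed$chrom, pos = tssbed$start,
                        gene = tssbed$name, strand = tssbed$strand,
                        stringsAsFactors = FALSE),
       orthologs = .read_tsv(file.path(dir, "orthologs.tsv")),
       tree = tree)
}

# roles.yaml is a flat mapping of three lists; parse with yaml when
# available, else with a minimal reader for the emitted layout
.read_roles <- function(path) {
  if (requireNamespace("yaml", quietly = TRUE))
    return(yaml::read_yaml(path))
  lines <- readLines(path)
  roles <- list(); current <- NULL
  for (ln in lines) {
    if (grepl("^\\S+:", ln)) {
      current <- sub(":.*$", "", ln)
      roles[[current]] <- character(0)
    } else if (grepl("^\\s+-\\s+", ln)) {
      roles[[current]] <- c(roles[[current]], sub("^\\s+-\\s+", "", ln))
    }
  }
  roles
}

#' Write a status matrix as TSV
#'
#' @param status a `cne_status` or character matrix.
#' @param path output file.
#' @export
write_status <- function(status, path) {
  if (inherits(status, "cne_status")) status <- status$status
  df <- data.frame(cne_id = rownames(status), status, check.names = FALSE)
  .write_tsv(df, path)
}

#' Read a status matrix written by [write_status()]
#'
#' @param path TSV file.
#' @return character matrix with CNE ids as row names.
#' @export
read_status <- function(path) {
  df <- .read_tsv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$cne_id
  m
}
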