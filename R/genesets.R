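# SNP <-> gene mapping, gene-set -> SNP-set construction, overlap statistics
# and random genic/non-genic SNP set generation.

#' Genic margins
#'
#' A SNP counts as genic when it lies within a gene body, within
#' `upstream_bp` of the transcription start, or within `downstream_bp` of the
#' transcription end. Margins are strand-aware by default: for a "-"-strand
#' gene the upstream margin extends from the higher-coordinate end.
#'
#' @param upstream_bp,downstream_bp margins in bp (both >= 0).
#' @return list of class `genic_margins`.
#' @export
genic_margins <- function(upstream_bp = 5000, downstream_bp = 1000) {
  stopifnot(upstream_bp >= 0, downstream_bp >= 0)
  structure(list(upstream_bp = upstream_bp, downstream_bp = downstream_bp),
            class = "genic_margins")
}

#' Classify SNPs as genic or non-genic and assign them to genes
#'
#' @param snps data.frame with `snp_id`, `chrom`, `pos` (1-based).
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive) and `strand` (`"+"`/`"-"`).
#' @param margins a [genic_margins()].
#' @param strand_aware if `FALSE`, apply the upstream margin to the `start`
#'   side and the downstream margin to the `end` side regardless of strand.
#' @return list of class `genic_classification`: `genic` (named logical, one
#'   entry per SNP), `assignments` (named list, gene id -> character vector of
#'   SNP ids; every gene present, possibly empty), `margins`.
#' @export
classify_genic <- function(snps, genes, margins = genic_margins(),
                           strand_aware = TRUE) {
  up <- margins$upstream_bp; down <- margins$downstream_bp
  minus <- strand_aware & genes$strand == "-"
  lo <- ifelse(minus, genes$start - down, genes$start - up)
  hi <- ifelse(minus, genes$end + up, genes$end + down)
  genic <- rep(FALSE, nrow(snps))
  assignments <- vector("list", nrow(genes))
  names(assignments) <- genes$gene_id
  for (g in seq_len(nrow(genes))) {
    hit <- snps$chrom == genes$chrom[g] & snps$pos >= lo[g] & snps$pos <= hi[g]
    assignments[[g]] <- snps$snp_id[hit]
    genic <- genic | hit
  }
  names(genic) <- snps$snp_id
  structure(list(genic = genic, assignments = assignments, margins = margins),
            class = "genic_classification")
}

#' Map a gene set to its SNP set
#'
#' Union of the SNPs assigned to any gene of the set, deduplicated. Genes
#' absent from the annotation produce a warning, not an error: curated sets
#' routinely cite genes missing from any one annotation.
#'
#' @param gene_set character vector of gene ids.
#' @param classification a [classify_genic()] result.
#' @return character vector of SNP ids (possibly empty).
#' @export
snps_for_gene_set <- function(gene_set, classification) {
  known <- gene_set %in% names(classification$assignments)
  if (any(!known))
    omniprs_warn(sprintf("%d gene(s) in set absent from annotation: %s",
                         sum(!known),
                         paste(head(gene_set[!known], 5), collapse = ", ")),
                 "omniprs_warning_unknown_gene")
  unique(unlist(classification$assignments[gene_set[known]], use.names = FALSE))
}

#' Intersection-lattice overlap statistics for gene sets
#'
#' For every non-empty combination of the supplied sets, counts the genes
#' belonging to exactly that combination (an exclusive Venn region) and
#' expresses it as a percentage of the union of all genes across the sets.
#'
#' @param gene_sets named list (>= 2) of character gene-id vectors.
#' @return data.frame with `region` (set names joined by `&`), `n_sets`
#'   (order of the region), `count` and `pct`. Percentages over all regions
#'   sum to 100.
#' @export
overlap_stats <- function(gene_sets) {
  k <- length(gene_sets)
  if (k < 2) omniprs_error("need at least 2 gene sets", "omniprs_error_config")
  if (is.null(names(gene_sets)))
    names(gene_sets) <- sprintf("set%d", seq_len(k))
  universe <- unique(unlist(gene_sets, use.names = FALSE))
  member <- vapply(gene_sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, names(gene_sets)))
  pattern <- apply(member, 1, function(r) paste(names(gene_sets)[r], collapse = "&"))
  combos <- unlist(lapply(seq_len(k), function(ord)
    utils::combn(names(gene_sets), ord, paste, collapse = "&")))
  counts <- table(factor(pattern, levels = combos))
  data.frame(region = combos,
             n_sets = lengths(strsplit(combos, "&", fixed = TRUE)),
             count = as.integer(counts),
             pct = if (length(universe)) 100 * as.integer(counts) / length(universe)
                   else rep(0, length(combos)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Serialize / read a SNP set as one-ID-per-line text
#' @param snp_set character vector of SNP ids.
#' @param path file path.
#' @export
write_snp_set <- function(snp_set, path) {
  writeLines(snp_set, path)
  invisible(path)
}

#' @rdname write_snp_set
#' @export
read_snp_set <- function(path) {
  ids <- readLines(path)
  ids[nzchar(ids)]
}

#' Draw random SNP sets from a pruned genic or non-genic pool
#'
#' Used for the omnigenic "floor" analysis: sets of quasi-independent SNPs
#' sampled without replacement within each set (with replacement across sets).
#' The pool must already be LD-pruned (conventionally at r^2 < 0.01).
#'
#' @param pool character vector of SNP ids to sample from.
#' @param n_sets number of sets.
#' @param set_size SNPs per set; truncated to the pool size with a warning.
#' @param seed stage seed.
#' @param prefix name prefix for the returned sets.
#' @return named list of character SNP-id vectors.
#' @export
draw_random_sets <- function(pool, n_sets = 50L, set_size = 5000L, seed = 1L,
                             prefix = "random") {
  stopifnot(n_sets >= 1, set_size >= 1)
  if (length(pool) == 0)
    omniprs_error("cannot draw random sets from an empty pool",
                  "omniprs_error_empty_pool")
  size <- min(set_size, length(pool))
  if (size < set_size)
    omniprs_warn(sprintf("pool (%d SNPs) smaller than requested set size %d; truncating",
                         length(pool), set_size),
                 "omniprs_warning_truncated_set")
  sets <- with_seed(as.integer(seed), {
    lapply(seq_len(n_sets), function(i) sample(pool, size))
  })
  names(sets) <- sprintf("%s%03d", prefix, seq_len(n_sets))
  sets
}
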