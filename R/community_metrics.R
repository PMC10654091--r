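#' Rarefy a feature table to a fixed read depth
#'
#' Samples with fewer than `depth` reads are dropped; every retained
#' sample is subsampled without replacement (multivariate hypergeometric)
#' to exactly `depth` reads. Deterministic for a fixed seed.
#'
#' @param table Samples x features matrix of non-negative integer counts
#'   (rows named by sample).
#' @param depth Target reads per sample, >= 1.
#' @param seed Integer seed.
#' @return List: `table` (rarefied matrix), `dropped` (character vector of
#'   sample ids below depth).
#' @export
rarefy <- function(table, depth, seed = 1) {
  table <- as.matrix(table)
  stopifnot(depth >= 1)
  if (any(table < 0) || any(table != round(table))) {
    stop("feature counts must be non-negative integers")
  }
  totals <- rowSums(table)
  keep <- totals >= depth
  dropped <- rownames(table)[!keep]
  kept <- table[keep, , drop = FALSE]
  if (!nrow(kept)) {
    warning("no samples reach rarefaction depth ", depth)
    return(list(table = kept, dropped = dropped))
  }
  # counts were validated above; silence vegan's observed-count heuristics
  rare <- with_seed(seed, suppressWarnings(vegan::rrarefy(kept, depth)))
  storage.mode(rare) <- "integer"
  list(table = rare, dropped = dropped)
}

#' Alpha diversity per sample
#'
#' Richness is the number of features with non-zero count; Shannon
#' diversity H = -sum p_i log2 p_i over the non-zero proportions (bits);
#' Pielou evenness is H / log2(richness), undefined (NA) for a
#' single-feature sample.
#'
#' @param table Samples x features count (or abundance) matrix.
#' @return Data frame: sample_id, richness, shannon, evenness.
#' @export
alpha_diversity <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0)) stop("all-zero sample: rarefy first")
  rows <- lapply(seq_len(nrow(table)), function(i) {
    x <- table[i, ]
    p <- x[x > 0] / sum(x)
    h <- -sum(p * log2(p))
    s <- length(p)
    data.frame(sample_id = rownames(table)[i] %||% as.character(i),
               richness = s, shannon = h,
               evenness = if (s > 1) h / log2(s) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = 1 - 2 sum_i min(x_i, y_i) / (sum x + sum y); zero on the
#' diagonal, symmetric, in [0, 1] for non-negative data.
#'
#' @param table Samples x features abundance matrix (>= 2 samples).
#' @return Symmetric numeric matrix of pairwise dissimilarities.
#' @export
bray_curtis <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) >= 2)
  if (any(table < 0)) stop("abundances must be non-negative")
  n <- nrow(table)
  d <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  tot <- rowSums(table)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- sum(pmin(table[i, ], table[j, ]))
      d[i, j] <- d[j, i] <- 1 - 2 * shared / (tot[i] + tot[j])
    }
  }
  d
}

#' Aggregate gene counts to KEGG Orthology groups
#'
#' Compresses gene-level counts to KO-level counts, splitting a gene's
#' count equally among the m KOs it maps to (count/m to each), so mapped
#' mass is conserved. Genes absent from the map (or mapped to zero KOs)
#' are dropped and tallied.
#'
#' @param gene_counts Named numeric vector of per-sample gene counts, or a
#'   samples x genes matrix.
#' @param mapping Data frame with columns `gene_id`, `ko_id` (many-to-many).
#' @return For a vector input: list `ko_counts` (named numeric vector),
#'   `unmapped_genes`, `unmapped_count`. For a matrix: list with
#'   `ko_counts` a samples x KO matrix and the same unmapped tallies.
#' @export
genes_to_kos <- function(gene_counts, mapping) {
  stopifnot(all(c("gene_id", "ko_id") %in% names(mapping)))
  if (is.matrix(gene_counts)) {
    per <- lapply(seq_len(nrow(gene_counts)), function(i) {
      genes_to_kos(gene_counts[i, ], mapping)
    })
    kos <- sort(unique(mapping$ko_id))
    mat <- t(vapply(per, function(p) {
      v <- stats::setNames(numeric(length(kos)), kos)
      v[names(p$ko_counts)] <- p$ko_counts
      v
    }, numeric(length(kos))))
    rownames(mat) <- rownames(gene_counts)
    return(list(ko_counts = mat,
                unmapped_genes = per[[1]]$unmapped_genes,
                unmapped_count = sum(vapply(per, `[[`, numeric(1), "unmapped_count"))))
  }
  genes <- names(gene_counts)
  stopifnot(!is.null(genes))
  mapped <- mapping[mapping$gene_id %in% genes, , drop = FALSE]
  multiplicity <- table(mapped$gene_id)
  unmapped <- setdiff(genes, names(multiplicity))
  share <- gene_counts[mapped$gene_id] / as.numeric(multiplicity[mapped$gene_id])
  ko_counts <- tapply(share, mapped$ko_id, sum)
  ko_counts <- stats::setNames(as.numeric(ko_counts), names(ko_counts))
  list(ko_counts = ko_counts,
       unmapped_genes = unmapped,
       unmapped_count = sum(gene_counts[unmapped]))
}
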