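#' Build promoter windows from a TSS table
#'
#' For a + strand gene with TSS at position t (0-based), the promoter is the
#' half-open window [t - upstream, t + downstream); minus-strand genes are
#' mirrored ([t - downstream, t + upstream)). Windows are clipped at zero
#' and, when chromosome lengths are supplied, at the chromosome end. The
#' result is returned as a named `GRanges` (1-based closed coordinates, the
#' exact image of the half-open windows).
#'
#' @param tss data.frame with columns `gene`, `chrom`, `pos` (0-based TSS),
#'   `strand` ("+"/"-").
#' @param upstream_bp,downstream_bp window extents (default 2000 each).
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return named `GRanges`, one promoter per gene.
#' @export
build_promoters <- function(tss, upstream_bp = 2000, downstream_bp = 2000,
                            chrom_lengths = NULL) {
  need <- c("gene", "chrom", "pos", "strand")
  if (!all(need %in% names(tss))) stopf("tss table needs columns %s", paste(need, collapse = ", "))
  if (any(tss$pos < 0)) stopf("TSS positions must be >= 0")
  if (!all(tss$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  dup <- tss$gene[duplicated(tss$gene)]
  if (length(dup)) {
    conflict <- unique(dup[vapply(dup, function(g)
      nrow(unique(tss[tss$gene == g, c("chrom", "pos", "strand")])) > 1, logical(1))])
    if (length(conflict))
      stopf("conflicting TSS for gene(s): %s", paste(conflict, collapse = ", "))
    tss <- tss[!duplicated(tss$gene), ]
  }
  plus <- tss$strand == "+"
  start0 <- ifelse(plus, tss$pos - upstream_bp, tss$pos - downstream_bp)
  end0 <- ifelse(plus, tss$pos + downstream_bp, tss$pos + upstream_bp)
  start0 <- pmax(start0, 0)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[tss$chrom]
    if (anyNA(lim)) stopf("chromosome lengths missing for some chromosomes")
    end0 <- pmin(end0, lim)
  }
  if (any(start0 >= end0)) stopf("degenerate promoter window after clipping")
  gr <- GenomicRanges::GRanges(tss$chrom,
                               IRanges::IRanges(start = start0 + 1L, end = end0),
                               strand = tss$strand)
  names(gr) <- tss$gene
  gr
}

#' Flag promoters overlapped by at least one peak
#'
#' A gene is "bound" when its promoter shares at least `min_overlap_bp`
#' base pairs with any peak. In half-open coordinates [0,10) and [10,20) do
#' not overlap. Chromosomes present in the promoters but absent from the
#' peak set simply yield unbound genes.
#'
#' @param promoters named `GRanges` from [build_promoters()].
#' @param peaks `GRanges` peak set (e.g. read with [read_bed()]).
#' @param min_overlap_bp minimum shared base pairs (default 1).
#' @return named logical vector, one entry per gene.
#' @export
overlap_flags <- function(promoters, peaks, min_overlap_bp = 1L) {
  # disjoint sequence levels (a chromosome with no peaks) are a benign,
  # documented case: those genes are simply unbound
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(promoters, peaks,
                                 minoverlap = min_overlap_bp,
                                 ignore.strand = TRUE))
  setNames(hits > 0, names(promoters))
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing k or more bound genes in a set of n drawn
#' without replacement from a universe of N genes of which K are bound:
#' p = sum_{i=k}^{min(n,K)} C(K,i) C(N-K,n-i) / C(N,n), accumulated in log
#' space for numerical stability.
#'
#' @param k observed bound genes in the set.
#' @param n set size.
#' @param K bound genes in the universe.
#' @param N universe size.
#' @return the upper-tail p-value in (0, 1].
#' @export
hypergeom_upper <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || n > N || K > N || k > min(n, K))
    stopf("impossible hypergeometric counts (k=%s, n=%s, K=%s, N=%s)", k, n, K, N)
  if (k <= 0) return(1)
  i <- k:min(n, K)
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(1, exp(logsumexp(lt)))
}

#' Promoter-occupancy enrichment simulation
#'
#' Tests whether a transcription factor's binding peaks preferentially
#' overlap the promoters of two marker gene sets. Group-1 genes are the
#' markers with avg_log2FC > 0 and group-2 genes those with avg_log2FC < 0.
#' As negative controls, `n_random` gene sets of `random_size` genes are
#' drawn (seeded, without replacement) from the universe excluding both
#' marker sets. For each peak set, one upper-tail hypergeometric test per
#' gene set is computed (marker sets + random sets, 12 tests with the
#' defaults) and Benjamini-Hochberg correction is applied within that peak
#' set's family of tests. The universe is the set of genes possessing
#' promoter coordinates; an optional ortholog table (columns `gene`,
#' `ortholog`) maps marker gene ids onto the promoter table's namespace.
#'
#' @param markers a `MarkerTable` from [find_markers()] (or a data.frame
#'   with `gene` and `avg_log2FC`).
#' @param promoters named `GRanges` from [build_promoters()].
#' @param peak_sets named list of `GRanges`, one per transcription factor.
#' @param n_random number of random control sets (default 10).
#' @param random_size genes per random set (default 150).
#' @param seed seed for the random draws.
#' @param set_labels length-2 labels for the marker sets
#'   (default c("FHF", "SHF")).
#' @param orthologs optional data.frame mapping `gene` -> `ortholog`.
#' @param min_overlap_bp passed to [overlap_flags()].
#' @return data.frame of class `EnrichmentTable`: `tf`, `set_name`, `N`,
#'   `K`, `n`, `k`, `p`, `p_adj`.
#' @export
run_occupancy_simulation <- function(markers, promoters, peak_sets,
                                     n_random = 10, random_size = 150,
                                     seed = 1L, set_labels = c("FHF", "SHF"),
                                     orthologs = NULL, min_overlap_bp = 1L) {
  if (!is.list(peak_sets) || is.null(names(peak_sets)))
    peak_sets <- setNames(list(peak_sets), "TF")
  universe <- names(promoters)
  map_genes <- function(g) {
    if (is.null(orthologs)) return(g)
    mapped <- orthologs$ortholog[match(g, orthologs$gene)]
    mapped[!is.na(mapped)]
  }
  set1 <- intersect(map_genes(markers$gene[markers$avg_log2FC > 0]), universe)
  set2 <- intersect(map_genes(markers$gene[markers$avg_log2FC < 0]), universe)
  sets <- list()
  if (length(set1)) sets[[set_labels[1]]] <- set1
  else warning(sprintf("empty %s marker set: skipped", set_labels[1]))
  if (length(set2)) sets[[set_labels[2]]] <- set2
  else warning(sprintf("empty %s marker set: skipped", set_labels[2]))

  pool <- setdiff(universe, union(set1, set2))
  if (length(pool) < random_size)
    stopf("universe too small for random draws of size %d", random_size)
  rand <- with_seed(seed, lapply(seq_len(n_random), function(i)
    sample(pool, random_size)))
  names(rand) <- sprintf("random_%02d", seq_len(n_random))
  sets <- c(sets, rand)

  N <- length(universe)
  out <- lapply(names(peak_sets), function(tf) {
    bound <- overlap_flags(promoters, peak_sets[[tf]], min_overlap_bp)
    K <- sum(bound)
    res <- do.call(rbind, lapply(names(sets), function(nm) {
      g <- sets[[nm]]
      data.frame(tf = tf, set_name = nm, N = N, K = K, n = length(g),
                 k = sum(bound[g]))
    }))
    res$p <- mapply(hypergeom_upper, res$k, res$n, MoreArgs = list(K = K, N = N))
    res$p_adj <- p.adjust(res$p, method = "BH")  # family = this TF's tests
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}
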