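#' Call allelic differences between two line sequences
#'
#' Globally aligns the two allele sequences (Needleman-Wunsch with affine
#' gaps: match 1, mismatch -1, gap open 5, gap extend 1) and walks the
#' alignment columns: mismatch columns become SNPs; each gap run becomes a
#' single insertion or deletion event, typed relative to the *second*
#' sequence, which plays the role of the declared reference line (bases
#' present in `seq_a` but absent from the reference are insertions; bases
#' of the reference absent from `seq_a` are deletions). Columns containing
#' `N` are skipped.
#'
#' Positions are reported on the reference coordinate system shifted by
#' `offset`: SNPs and deletions at the (first) affected reference base,
#' insertions at the reference base immediately preceding the inserted run
#' (left-aligned anchoring).
#'
#' @param seq_a,seq_b Nucleotide strings over `A`, `C`, `G`, `T`, `N`;
#'   `seq_b` is the reference.
#' @param offset Genomic coordinate of the first base of `seq_b`.
#' @return Tibble `type`, `genomic_position`, `hab_allele`, `lab_allele`
#'   (the `seq_a` / `seq_b` alleles; gap runs are reported as the run's
#'   bases on the side that carries them and `""` on the other).
#' @examples
#' diff_alleles("ACGTACGTAA", "ACGTCCGTAA", offset = 100)
#' @export
diff_alleles <- function(seq_a, seq_b, offset = 1L) {
  seq_a <- toupper(as.character(seq_a)); seq_b <- toupper(as.character(seq_b))
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) abort("empty sequence")
  if (grepl("[^ACGTN]", seq_a) || grepl("[^ACGTN]", seq_b)) {
    abort("sequences must be over {A,C,G,T,N}")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 1)
  ga <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  gb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ref_pos <- cumsum(gb != "-")  # reference coordinate at each column
  records <- list()
  i <- 1L
  n_col <- length(ga)
  while (i <= n_col) {
    a <- ga[i]; b <- gb[i]
    if (a == "N" || b == "N") { i <- i + 1L; next }
    if (a != "-" && b != "-") {
      if (a != b) {
        records[[length(records) + 1]] <- tibble::tibble(
          type = "SNP", genomic_position = offset + ref_pos[i] - 1L,
          hab_allele = a, lab_allele = b)
      }
      i <- i + 1L
    } else if (b == "-") {
      j <- i
      while (j <= n_col && gb[j] == "-") j <- j + 1L
      run <- paste(ga[i:(j - 1)], collapse = "")
      anchor <- if (i > 1) ref_pos[i - 1] else 0L
      records[[length(records) + 1]] <- tibble::tibble(
        type = "insertion", genomic_position = offset + anchor - 1L,
        hab_allele = run, lab_allele = "")
      i <- j
    } else {
      j <- i
      while (j <= n_col && ga[j] == "-") j <- j + 1L
      run <- paste(gb[i:(j - 1)], collapse = "")
      records[[length(records) + 1]] <- tibble::tibble(
        type = "deletion", genomic_position = offset + ref_pos[i] - 1L,
        hab_allele = "", lab_allele = run)
      i <- j
    }
  }
  if (length(records) == 0) {
    return(tibble::tibble(type = character(), genomic_position = integer(),
                          hab_allele = character(), lab_allele = character()))
  }
  dplyr::bind_rows(records)
}

#' Plant variants into a synthetic gene locus
#'
#' Generates a variant table from explicit cluster and scatter
#' specifications against a [gene_model()]: clusters place `n` variants
#' evenly across a window of stated width inside a named region (so a
#' sliding window of that width recovers exactly `n`), scatter
#' specifications place variants at seeded-uniform unique positions within
#' their region. Positions are unique across the whole table.
#'
#' @param model A [gene_model()].
#' @param clusters Tibble with columns `region` (label such as
#'   `"intron-3"`), `start_rel` (window start relative to the TSS), `width`
#'   (bp), `n`; optional `types` list-column of per-variant types.
#' @param scatter Tibble with columns `region`, `n`; optional `types`.
#' @param seed Integer seed for the scatter draws.
#' @return An annotated variant tibble (see [annotate_variants()]) with
#'   `hab_allele` / `lab_allele` filled from a deterministic rotation.
#' @export
synth_variant_table <- function(model, clusters = NULL, scatter = NULL,
                                seed = 1L) {
  stopifnot(inherits(model, "gene_model"))
  rows <- list()
  if (!is.null(clusters) && nrow(clusters) > 0) {
    assert_cols(clusters, c("region", "start_rel", "width", "n"), "clusters")
    for (k in seq_len(nrow(clusters))) {
      sp <- region_span(model, clusters$region[k])
      width <- clusters$width[k]; n <- clusters$n[k]
      if (width > sp[2] - sp[1] + 1) {
        abort(sprintf("cluster in %s wider (%d bp) than its host region (%d bp)",
                      clusters$region[k], width, sp[2] - sp[1] + 1))
      }
      start <- model$tss + clusters$start_rel[k]
      if (start < sp[1] || start + width - 1 > sp[2]) {
        abort(sprintf("cluster window does not lie inside %s", clusters$region[k]))
      }
      pos <- start + round((width - 1) * (seq_len(n) - 1) / (n - 1))
      types <- cluster_types(clusters, k, n)
      rows[[length(rows) + 1]] <- tibble::tibble(type = types,
                                                 genomic_position = as.integer(pos))
    }
  }
  if (!is.null(scatter) && nrow(scatter) > 0) {
    assert_cols(scatter, c("region", "n"), "scatter")
    used <- if (length(rows)) dplyr::bind_rows(rows)$genomic_position else integer()
    rows_sc <- with_seed(derive_seed(seed, "variant-scatter"), {
      purrr::map(seq_len(nrow(scatter)), function(k) {
        sp <- region_span(model, scatter$region[k])
        avail <- setdiff(seq(sp[1], sp[2]), used)
        pos <- sort(sample(avail, scatter$n[k]))
        used <<- c(used, pos)
        tibble::tibble(type = cluster_types(scatter, k, scatter$n[k]),
                       genomic_position = as.integer(pos))
      })
    })
    rows <- c(rows, rows_sc)
  }
  if (length(rows) == 0) {
    v <- tibble::tibble(type = character(), genomic_position = integer(),
                        hab_allele = character(), lab_allele = character())
    return(annotate_variants(v, model))
  }
  v <- dplyr::bind_rows(rows)
  if (anyDuplicated(v$genomic_position)) abort("planted positions collide")
  v <- fill_alleles(v)
  annotate_variants(v, model)
}

cluster_types <- function(spec, k, n) {
  if ("types" %in% names(spec) && !is.null(spec$types[[k]])) {
    t <- spec$types[[k]]
    if (length(t) != n) abort("types entry must match n")
    t
  } else {
    rep("SNP", n)
  }
}

# Deterministic allele assignment: SNPs rotate through base pairs,
# insertions carry extra bases in the HAB allele, deletions in the LAB
# allele (the reader preserves whatever labels a real table carries).
fill_alleles <- function(v) {
  snp_pairs <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"),
                    c("A", "C"), c("G", "T"))
  ins_runs <- c("CT", "AG", "TGA")
  is_snp <- v$type == "SNP"
  idx <- cumsum(is_snp)
  v$hab_allele <- v$lab_allele <- NA_character_
  for (i in seq_len(nrow(v))) {
    if (v$type[i] == "SNP") {
      pr <- snp_pairs[[(idx[i] - 1) %% length(snp_pairs) + 1]]
      v$hab_allele[i] <- pr[1]; v$lab_allele[i] <- pr[2]
    } else if (v$type[i] == "insertion") {
      run <- ins_runs[(i - 1) %% length(ins_runs) + 1]
      v$hab_allele[i] <- run; v$lab_allele[i] <- ""
    } else {
      run <- ins_runs[(i - 1) %% length(ins_runs) + 1]
      v$hab_allele[i] <- ""; v$lab_allele[i] <- run
    }
  }
  v
}

#' Build a line-allele sequence pair carrying planted variants
#'
#' Constructs a random reference (LAB-line) sequence and applies the
#' variant table to produce the HAB-line allele: SNPs substitute the HAB
#' base, insertions add the HAB run after its anchor base, deletions remove
#' the LAB run starting at the variant position. Useful for round-trip
#' testing of [diff_alleles()].
#'
#' @param variants Variant tibble (`type`, `genomic_position`,
#'   `hab_allele`, `lab_allele`) with positions in `offset`-based
#'   coordinates.
#' @param length_bp Length of the reference sequence.
#' @param offset Genomic coordinate of the first reference base.
#' @param seed Seed for the reference draw.
#' @return List with `hab`, `lab` (character sequences).
#' @export
synth_allele_pair <- function(variants, length_bp, offset = 1L, seed = 1L) {
  pos0 <- variants$genomic_position - offset + 1L
  if (any(pos0 < 1 | pos0 > length_bp)) abort("variant positions outside sequence")
  lab <- with_seed(derive_seed(seed, "allele-ref"), {
    sample(c("A", "C", "G", "T"), length_bp, replace = TRUE)
  })
  # impose LAB alleles on the reference
  v <- variants[order(pos0), ]
  p0 <- sort(pos0)
  for (i in seq_len(nrow(v))) {
    if (v$type[i] == "SNP") {
      lab[p0[i]] <- v$lab_allele[i]
    } else if (v$type[i] == "deletion") {
      run <- strsplit(v$lab_allele[i], "")[[1]]
      lab[p0[i] + seq_along(run) - 1] <- run
    }
  }
  # derive HAB from LAB
  take <- function(from, to) {
    if (to < from) "" else paste(lab[from:to], collapse = "")
  }
  hab_parts <- character(0)
  cursor <- 1L
  for (i in seq_len(nrow(v))) {
    if (v$type[i] == "SNP") {
      hab_parts <- c(hab_parts, take(cursor, p0[i] - 1L), v$hab_allele[i])
      cursor <- p0[i] + 1L
    } else if (v$type[i] == "insertion") {
      hab_parts <- c(hab_parts, take(cursor, p0[i]), v$hab_allele[i])
      cursor <- p0[i] + 1L
    } else {
      hab_parts <- c(hab_parts, take(cursor, p0[i] - 1L))
      cursor <- p0[i] + nchar(v$lab_allele[i])
    }
  }
  if (cursor <= length_bp) {
    hab_parts <- c(hab_parts, paste(lab[seq(cursor, length_bp)], collapse = ""))
  }
  list(hab = paste(hab_parts, collapse = ""), lab = paste(lab, collapse = ""))
}
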