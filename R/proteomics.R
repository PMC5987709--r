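# Six-plex TMT reporter quantitation: channel normalization, Top3
# interprotein abundance, ratio/significance analysis, ratio-density and
# heat-map matrices, and protein-cluster enrichment.
#
# A peptide table is a data.frame with protein_id, peptide_id and six
# reporter-intensity columns c1..c6 (arbitrary units >= 0; zero means
# not detected). Sample metadata maps each channel to a group label and a
# measured input protein concentration (mg/ml).

CHANNELS <- paste0("c", 1:6)

#' Construct sample metadata for a 6-plex design
#'
#' @param groups character vector of 6 group labels (exactly 2 distinct
#'   labels, 3 channels each; e.g. `"ss"` and `"TNFa"`), in channel order
#'   c1..c6.
#' @param concentrations measured input protein concentrations (mg/ml) per
#'   channel, all > 0.
#' @return data.frame with columns `channel`, `group`, `concentration`.
#' @export
sample_meta <- function(groups, concentrations) {
  if (length(groups) != 6L || length(concentrations) != 6L) {
    stop_bad("exactly 6 channels required")
  }
  tab <- table(groups)
  if (length(tab) != 2L || any(tab != 3L)) {
    stop_bad("design must have 2 groups with 3 channels each")
  }
  assert_finite_num(concentrations, "concentrations")
  if (any(concentrations <= 0)) stop_bad("concentrations must be > 0")
  data.frame(channel = CHANNELS, group = as.character(groups),
             concentration = as.numeric(concentrations),
             stringsAsFactors = FALSE)
}

validate_peptide_table <- function(table) {
  need <- c("protein_id", "peptide_id", CHANNELS)
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop_bad("peptide table is missing column(s): %s", paste(miss, collapse = ", "))
  }
  extra <- grep("^c[0-9]+$", names(table), value = TRUE)
  if (!setequal(extra, CHANNELS)) {
    stop_bad("peptide table must have exactly 6 reporter channels c1..c6")
  }
  m <- as.matrix(as.data.frame(table)[, CHANNELS])
  if (anyNA(m) || any(!is.finite(m)) || any(m < 0)) {
    stop_bad("reporter intensities must be finite and >= 0")
  }
  invisible(table)
}

meta_groups <- function(meta) {
  split(meta$channel, meta$group)
}

#' Median-normalize reporter channels and apply concentration scaling
#'
#' Each reporter channel is rescaled so all channels share an equal median
#' intensity (zeros are non-detections and excluded from medians), then
#' multiplied by the channel's measured input protein concentration divided
#' by the minimum concentration of the six samples, making reporter
#' intensities proportional to the measured protein amounts. The common
#' median target is the minimum of the per-channel medians, which makes the
#' operation exactly idempotent.
#'
#' @param table peptide table (see module header).
#' @param meta [sample_meta()] data.frame.
#' @return the peptide table with rescaled channel columns.
#' @export
normalize_channels <- function(table, meta) {
  validate_peptide_table(table)
  out <- table
  meds <- vapply(CHANNELS, function(ch) {
    v <- table[[ch]]
    v <- v[v > 0]
    if (!length(v)) stop_bad("channel %s has all-zero intensities", ch)
    median(v)
  }, numeric(1))
  target <- min(meds)
  conc <- setNames(meta$concentration, meta$channel)[CHANNELS]
  conc_scale <- conc / min(conc)
  for (ch in CHANNELS) {
    out[[ch]] <- table[[ch]] * (target / meds[[ch]]) * conc_scale[[ch]]
  }
  out
}

#' Top3 interprotein abundance
#'
#' Protein abundance per channel is the mean of the three largest peptide
#' intensities of that protein in that channel; proteins with fewer than
#' three detected peptides use the mean of all detected ones. Zero
#' intensities are non-detections and are excluded; a protein undetected in
#' a channel gets NA there.
#'
#' @param table (normalized) peptide table.
#' @return numeric matrix, proteins x 6 channels, rownames = protein ids.
#' @export
top3 <- function(table) {
  validate_peptide_table(table)
  dt <- data.table::as.data.table(table)
  res <- dt[, lapply(.SD, function(v) {
    v <- v[v > 0]
    if (!length(v)) return(NA_real_)
    mean(sort(v, decreasing = TRUE)[seq_len(min(3L, length(v)))])
  }), by = protein_id, .SDcols = CHANNELS]
  m <- as.matrix(res[, CHANNELS, with = FALSE])
  rownames(m) <- res$protein_id
  m
}

#' Protein ratios and significance calls
#'
#' For each protein: the treated/reference abundance ratio (means of Top3
#' abundances over the three channels of each group), `p_sample` from a
#' two-sided Welch t-test on log10 abundances (3 vs 3), and `p_ratio` from
#' a one-sample t-test of peptide-level log10 treated/reference ratios
#' against 0, Benjamini-Hochberg adjusted across proteins. A protein is
#' significant iff `p_sample < alpha` and the adjusted `p_ratio < alpha`.
#' Proteins with a single usable peptide get `p_ratio` NA and are never
#' flagged. This decision rule replaces the isobar noise model; tests and
#' `alpha` are configurable.
#'
#' @param abundance Top3 matrix from [top3()] (on the normalized table).
#' @param table the normalized peptide table (for peptide-level ratios).
#' @param meta [sample_meta()] data.frame.
#' @param treated,reference group labels; by default the group of channel
#'   c1 is the reference and the group of channel c6 is treated (the
#'   conventional channel layout; pass both explicitly in analyses).
#' @param alpha significance level for both p-values (default 0.05).
#' @return data.table with one row per protein: `protein_id`, group mean
#'   abundances, `ratio`, `log10_ratio`, `p_sample`, `p_ratio`,
#'   `p_ratio_fdr`, `significant`.
#' @export
ratios_and_significance <- function(abundance, table, meta,
                                    treated = NULL, reference = NULL,
                                    alpha = 0.05) {
  validate_peptide_table(table)
  if (is.null(reference)) reference <- meta$group[1]
  if (is.null(treated)) treated <- setdiff(unique(meta$group), reference)[1]
  grp <- meta_groups(meta)
  ref_ch <- grp[[reference]]
  trt_ch <- grp[[treated]]
  if (is.null(ref_ch) || is.null(trt_ch)) stop_bad("unknown group label")

  mean_ref <- rowMeans(abundance[, ref_ch, drop = FALSE], na.rm = TRUE)
  mean_trt <- rowMeans(abundance[, trt_ch, drop = FALSE], na.rm = TRUE)
  ratio <- mean_trt / mean_ref
  ratio[!is.finite(ratio)] <- NA_real_

  p_sample <- vapply(seq_len(nrow(abundance)), function(i) {
    a <- abundance[i, trt_ch]
    b <- abundance[i, ref_ch]
    a <- a[is.finite(a) & a > 0]
    b <- b[is.finite(b) & b > 0]
    welch_p(log10(a), log10(b))
  }, numeric(1))

  # peptide-level log10 ratios (group means per peptide over detected values)
  tbl <- as.data.frame(table)
  tmat <- as.matrix(tbl[, trt_ch, drop = FALSE])
  rmat <- as.matrix(tbl[, ref_ch, drop = FALSE])
  tmat[tmat == 0] <- NA
  rmat[rmat == 0] <- NA
  r_pep <- log10(rowMeans(tmat, na.rm = TRUE) / rowMeans(rmat, na.rm = TRUE))
  pep_dt <- data.table::data.table(protein_id = table$protein_id, r = r_pep)
  pep_ratio <- pep_dt[, .(p_ratio = one_sample_p(r[is.finite(r)])),
                      by = protein_id]

  out <- data.table::data.table(
    protein_id = rownames(abundance),
    mean_reference = mean_ref,
    mean_treated = mean_trt,
    ratio = ratio,
    log10_ratio = log10(ratio),
    p_sample = p_sample
  )
  out <- pep_ratio[out, on = "protein_id"]
  data.table::setcolorder(out, c("protein_id", "mean_reference",
                                 "mean_treated", "ratio", "log10_ratio",
                                 "p_sample", "p_ratio"))
  out[, p_ratio_fdr := p.adjust(p_ratio, method = "BH")]
  out[, significant := !is.na(p_sample) & !is.na(p_ratio_fdr) &
        p_sample < alpha & p_ratio_fdr < alpha]
  data.table::setattr(out, "groups",
                      list(treated = treated, reference = reference))
  out[]
}

#' Ratio-density histogram and overall fold change
#'
#' Histogram of per-protein log10 ratios (relative protein counts per bin)
#' plus the overall abundance fold change, defined as the summed treated
#' group-mean abundance over the summed reference group-mean abundance.
#'
#' @param quant output of [ratios_and_significance()].
#' @param breaks number of histogram bins (default 40) or a vector of
#'   break points on the log10 scale.
#' @return list with `histogram` (data.table: `bin_lo`, `bin_hi`,
#'   `bin_mid`, `count`, `fraction`) and `overall_fold_change`.
#' @export
ratio_density <- function(quant, breaks = 40) {
  lr <- quant$log10_ratio
  lr <- lr[is.finite(lr)]
  if (!length(lr)) stop_bad("no finite ratios")
  h <- graphics::hist(lr, breaks = breaks, plot = FALSE)
  ok <- is.finite(quant$mean_treated) & is.finite(quant$mean_reference)
  overall <- sum(quant$mean_treated[ok]) / sum(quant$mean_reference[ok])
  list(
    histogram = data.table::data.table(
      bin_lo = head(h$breaks, -1), bin_hi = tail(h$breaks, -1),
      bin_mid = h$mids, count = h$counts,
      fraction = h$counts / sum(h$counts)
    ),
    overall_fold_change = overall
  )
}

#' Heat-map value matrix
#'
#' value(protein, sample) = log10(abundance / mean abundance of the
#' reference-group samples of that protein). Proteins with a zero or
#' missing reference mean get NA.
#'
#' @param abundance Top3 matrix.
#' @param meta [sample_meta()] data.frame.
#' @param reference reference group label (default the group of channel
#'   c1, conventionally the steady-state samples).
#' @return numeric matrix, proteins x channels, on the log10 scale.
#' @export
heatmap_matrix <- function(abundance, meta, reference = NULL) {
  if (is.null(reference)) reference <- meta$group[1]
  ref_ch <- meta_groups(meta)[[reference]]
  if (is.null(ref_ch)) stop_bad("unknown reference group '%s'", reference)
  ref_mean <- rowMeans(abundance[, ref_ch, drop = FALSE], na.rm = TRUE)
  ref_mean[!is.finite(ref_mean) | ref_mean <= 0] <- NA_real_
  log10(sweep(abundance, 1, ref_mean, "/"))
}

#' Read protein-cluster definitions in GMT format
#'
#' One cluster per line: name, description, then member ids, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors of protein ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_bad("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    ids <- f[-(1:2)]
    ids <- ids[nzchar(ids)]
    if (length(f) < 3L || !length(ids)) {
      stop_bad("GMT line %d ('%s') defines an empty cluster", i, f[1])
    }
    out[[f[1]]] <- unique(ids)
  }
  out
}

#' Write cluster definitions in GMT format
#'
#' @param clusters named list of character vectors.
#' @param path output file.
#' @param descriptions optional per-cluster description strings.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(clusters, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("", length(clusters))
  lines <- vapply(seq_along(clusters), function(i) {
    paste(c(names(clusters)[i], descriptions[i], clusters[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Cluster fold enrichment over all quantified proteins
#'
#' Per cluster and per group: the mean interprotein abundance of the
#' cluster members divided by the mean interprotein abundance of all
#' quantified proteins (group abundances are channel means of Top3 values).
#' A Welch t-test of the cluster members against all proteins (on log10
#' group abundances) is attached as the comparison statistic. Unmatched
#' cluster ids are reported in the `unmatched` attribute; a cluster with no
#' quantified member is an error naming the cluster.
#'
#' @param abundance Top3 matrix.
#' @param clusters named list of protein-id sets (see [read_gmt()]).
#' @param meta [sample_meta()] data.frame.
#' @return data.table: `cluster`, `group`, `n_members`, `mean_cluster`,
#'   `mean_all`, `enrichment`, `p_value`; attribute `unmatched` lists ids
#'   absent from the abundance matrix per cluster.
#' @export
cluster_enrichment <- function(abundance, clusters, meta) {
  if (!length(clusters)) stop_bad("no clusters given")
  grp <- meta_groups(meta)
  group_abund <- vapply(grp, function(ch) {
    rowMeans(abundance[, ch, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(abundance)))
  rownames(group_abund) <- rownames(abundance)
  unmatched <- list()
  rows <- list()
  for (cl in names(clusters)) {
    ids <- clusters[[cl]]
    hit <- intersect(ids, rownames(abundance))
    unmatched[[cl]] <- setdiff(ids, rownames(abundance))
    if (!length(hit)) stop_bad("cluster '%s' has no quantified members", cl)
    for (g in names(grp)) {
      all_v <- group_abund[, g]
      all_v <- all_v[is.finite(all_v)]
      cl_v <- group_abund[hit, g]
      cl_v <- cl_v[is.finite(cl_v)]
      rows[[length(rows) + 1L]] <- data.table::data.table(
        cluster = cl, group = g, n_members = length(hit),
        mean_cluster = mean(cl_v), mean_all = mean(all_v),
        enrichment = mean(cl_v) / mean(all_v),
        p_value = welch_p(log10(cl_v[cl_v > 0]), log10(all_v[all_v > 0]))
      )
    }
  }
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "unmatched", unmatched)
  out[]
}
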