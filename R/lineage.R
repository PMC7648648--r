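## Lineage-tracing clone statistics: per-condition category tallies with
## S.E.M. across animals, per-fly clone frequencies, pooled-variance
## Student's t comparisons, cell-population censuses and the dataset
## coverage estimate.

.check_clone_table <- function(table, categories = NULL) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  need <- c("fly_id", "condition", "ovariole_id", "category")
  if (!all(need %in% names(table))) {
    stop("clone table needs columns: ", paste(need, collapse = ", "))
  }
  if (!nrow(table)) stop("clone table is empty")
  if (!is.null(categories)) {
    bad <- setdiff(unique(table$category), categories)
    if (length(bad)) {
      stop("unknown clone category: ", paste(bad, collapse = ", "))
    }
  }
  key <- paste(table$condition, table$fly_id, table$ovariole_id)
  if (anyDuplicated(key)) stop("duplicated (fly, ovariole) within a condition")
  table
}

#' Tally clone categories per condition
#'
#' Counts ovarioles per category and condition, with proportions over all
#' ovarioles of the condition and the S.E.M. of the per-fly proportions
#' (SD across flies / sqrt(number of flies)); with a single fly the S.E.M.
#' is undefined and reported as `NA` with a warning. The category set is
#' part of the input schema (it differs between experiments), not a
#' constant.
#'
#' @param table data.frame with columns `fly_id`, `condition`,
#'   `ovariole_id`, `category`.
#' @param categories declared ordered category vocabulary; rows outside it
#'   are an error. Defaults to the categories present.
#' @return data.frame: condition, category, n_ovarioles, proportion, sem.
#' @export
tally_clone_categories <- function(table, categories = NULL) {
  table <- .check_clone_table(table, categories)
  if (is.null(categories)) categories <- sort(unique(table$category))
  out <- list()
  for (cond in unique(table$condition)) {
    sub <- table[table$condition == cond, ]
    total <- nrow(sub)
    flies <- unique(sub$fly_id)
    if (length(flies) < 2L) {
      warning(sprintf("condition '%s' has a single fly; S.E.M. undefined", cond))
    }
    for (cat in categories) {
      hit <- sub$category == cat
      per_fly <- vapply(flies, function(f) {
        mean(sub$category[sub$fly_id == f] == cat)
      }, numeric(1))
      sem <- if (length(flies) >= 2L) {
        stats::sd(per_fly) / sqrt(length(flies))
      } else {
        NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, category = cat, n_ovarioles = sum(hit),
        proportion = sum(hit) / total, sem = sem, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-fly clone frequencies
#'
#' For every fly, the fraction of its ovarioles falling in any of the
#' categories of interest (e.g. "FSC clones" plus "transient clones" to
#' quantify follicle-lineage labelling). The fly is the unit of
#' replication for downstream comparisons.
#'
#' @param table clone table (see [tally_clone_categories()]).
#' @param categories_of_interest categories counted as events.
#' @return data.frame: condition, fly_id, n_ovarioles, frequency.
#' @export
per_fly_frequency <- function(table, categories_of_interest) {
  table <- .check_clone_table(table)
  out <- list()
  for (cond in unique(table$condition)) {
    sub <- table[table$condition == cond, ]
    for (f in unique(sub$fly_id)) {
      rows <- sub[sub$fly_id == f, ]
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, fly_id = f, n_ovarioles = nrow(rows),
        frequency = mean(rows$category %in% categories_of_interest),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Two-sided Student's t comparison of clone frequencies
#'
#' Classical two-sample pooled-variance Student's t-test (two-sided),
#' `df = n1 + n2 - 2`, computed in closed form. Welch's unequal-variance
#' variant is available behind a flag. Degenerate inputs follow fixed
#' conventions: zero pooled variance with equal means gives t = 0, p = 1;
#' with unequal means, p = 0 with a warning.
#'
#' @param freqs_a,freqs_b numeric vectors (>= 2 values each), e.g. per-fly
#'   frequencies of two conditions.
#' @param welch use Welch's t instead of the pooled-variance test.
#' @return List: `t`, `df`, `p_value`.
#' @export
compare_frequencies <- function(freqs_a, freqs_b, welch = FALSE) {
  n1 <- length(freqs_a)
  n2 <- length(freqs_b)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values")
  m1 <- mean(freqs_a)
  m2 <- mean(freqs_b)
  v1 <- stats::var(freqs_a)
  v2 <- stats::var(freqs_b)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    if (se2 == 0) {
      if (m1 == m2) return(list(t = 0, df = n1 + n2 - 2, p_value = 1))
      warning("zero variance with unequal means")
      return(list(t = Inf * sign(m1 - m2), df = n1 + n2 - 2, p_value = 0))
    }
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    t <- (m1 - m2) / sqrt(se2)
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    if (sp2 == 0) {
      if (m1 == m2) return(list(t = 0, df = df, p_value = 1))
      warning("zero pooled variance with unequal means")
      return(list(t = Inf * sign(m1 - m2), df = df, p_value = 0))
    }
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df = df))
}

#' Cell-population census summary
#'
#' Per-marker mean and sample SD (n - 1 denominator) of cell counts per
#' germarium, e.g. the number of escort cells expressing each marker.
#' A marker observed in a single germarium reports its mean with an `NA`
#' SD and a warning.
#'
#' @param census data.frame with columns `germarium_id`, `marker`,
#'   `cell_count` (non-negative integers).
#' @return data.frame: marker, n_germaria, mean, sd.
#' @export
population_census <- function(census) {
  census <- as.data.frame(census, stringsAsFactors = FALSE)
  need <- c("germarium_id", "marker", "cell_count")
  if (!all(need %in% names(census))) {
    stop("census needs columns: ", paste(need, collapse = ", "))
  }
  if (any(census$cell_count < 0) || any(census$cell_count != round(census$cell_count))) {
    stop("cell counts must be non-negative integers")
  }
  out <- lapply(unique(census$marker), function(mk) {
    x <- census$cell_count[census$marker == mk]
    if (length(x) < 2L) {
      warning(sprintf("marker '%s' has a single germarium; SD undefined", mk))
    }
    data.frame(marker = mk, n_germaria = length(x), mean = mean(x),
               sd = if (length(x) >= 2L) stats::sd(x) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Difference between two marker population sizes
#'
#' Estimates the size of the sub-population expressing marker A but not
#' marker B as `mean(A) - mean(B)` — e.g. the GstS1+ cas- central escort
#' cells as the GstS1 census minus the cas census — optionally rounded to
#' the nearest integer cell count.
#'
#' @param census raw census table or a [population_census()] summary.
#' @param marker_a,marker_b marker names.
#' @param integer round the difference to the nearest whole cell.
#' @return Numeric difference estimate.
#' @export
census_difference <- function(census, marker_a, marker_b, integer = FALSE) {
  stats <- if (all(c("marker", "mean") %in% names(census))) census else
    population_census(census)
  ia <- match(marker_a, stats$marker)
  ib <- match(marker_b, stats$marker)
  if (is.na(ia)) stop(sprintf("marker '%s' absent from the census", marker_a))
  if (is.na(ib)) stop(sprintf("marker '%s' absent from the census", marker_b))
  d <- stats$mean[ia] - stats$mean[ib]
  if (integer) round(d) else d
}

#' Sequencing coverage of a repeated anatomical unit
#'
#' Ratio of profiled cells to the cell count of one unit (e.g. ~14,000
#' profiled cells over ~6,700 cells per ovariole gives > 2x coverage).
#'
#' @param total_cells cells in the dataset.
#' @param cells_per_unit cells per anatomical unit (> 0).
#' @return `total_cells / cells_per_unit`.
#' @export
coverage_ratio <- function(total_cells, cells_per_unit) {
  if (cells_per_unit <= 0) stop("cells_per_unit must be > 0")
  total_cells / cells_per_unit
}
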