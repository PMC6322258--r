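#' Distribution and probability gain of an indicator over CAEs vs non-CAEs
#'
#' Bins the indicator's value spectrum into `n_bins` equal-width intervals
#' over [0, max] (one bin per integer value for TF) and computes, per bin,
#' the prevalence probability of CAEs, of non-CAEs, and the probability
#' gain: the bin's CAE rate minus the overall CAE rate. A positive gain in
#' a bin means CAEs are over-represented there.
#'
#' @param values Numeric indicator values, one per (entity, article) pair.
#' @param is_cae Logical vector: is the pair a gold CAE?
#' @param indicator Indicator name (stored; `"tf"` switches to integer
#'   bins).
#' @param n_bins Number of intervals (default 20).
#' @return A `cae_profile` tibble: `bin`, `lower`, `upper`, `n_cae`,
#'   `n_noncae`, `n`, `p_cae`, `p_noncae`, `prob_gain` (NA in empty bins);
#'   attributes `overall_cae_rate`, `indicator`.
#' @export
bin_indicator_distribution <- function(values, is_cae, indicator = "indicator",
                                       n_bins = 20L) {
  stopifnot(length(values) == length(is_cae), all(is.finite(values)))
  if (!any(is_cae) || all(is_cae)) {
    stop("need both CAEs and non-CAEs to profile an indicator", call. = FALSE)
  }
  if (identical(indicator, "tf")) {
    vmax <- max(values)
    lower <- seq_len(vmax)
    upper <- lower
    idx <- pmin(pmax(round(values), 1L), vmax)
  } else {
    vmax <- max(values)
    if (vmax <= 0) vmax <- 1
    edges <- seq(0, vmax, length.out = n_bins + 1L)
    lower <- edges[-length(edges)]
    upper <- edges[-1]
    idx <- pmin(pmax(ceiling(values / vmax * n_bins), 1L), n_bins)
  }
  nb <- length(lower)
  n_cae <- tabulate(idx[is_cae], nbins = nb)
  n_non <- tabulate(idx[!is_cae], nbins = nb)
  n <- n_cae + n_non
  rate <- sum(is_cae) / length(is_cae)
  pg <- ifelse(n > 0, n_cae / n - rate, NA_real_)
  out <- tibble::tibble(bin = seq_len(nb), lower = lower, upper = upper,
                        n_cae = n_cae, n_noncae = n_non, n = n,
                        p_cae = n_cae / sum(is_cae),
                        p_noncae = n_non / sum(!is_cae),
                        prob_gain = pg)
  structure(out, overall_cae_rate = rate, indicator = indicator,
            class = c("cae_profile", class(out)))
}

#' Positional distribution of CAE vs non-CAE mentions
#'
#' Assigns every mention to one of `n_parts` relative-position parts of its
#' abstract (measured in words or sentences); title mentions form a
#' separate leading category. Prevalence probabilities and probability gain
#' are computed per part as in [bin_indicator_distribution()].
#'
#' @param annotated A `cae_annotated_corpus`.
#' @param gold A `cae_gold` labelling CAEs.
#' @param unit `"words"` or `"sentences"`.
#' @param n_parts Number of abstract parts (default 20).
#' @return A `cae_profile` tibble whose first row is the TITLE category
#'   (`bin` 0) followed by parts 1..n_parts.
#' @export
positional_distribution <- function(annotated, gold,
                                    unit = c("words", "sentences"),
                                    n_parts = 20L) {
  unit <- match.arg(unit)
  part <- integer(); lab <- logical()
  for (aid in names(annotated)) {
    a <- annotated[[aid]]
    if (nrow(a$mentions) == 0L) next
    gc <- gold[[aid]] %||% character()
    sl <- lengths(a$segmented$sentence_tokens)
    abs_len <- sum(sl)
    n_sent <- a$segmented$n_sentences
    starts <- cumsum(c(0L, sl))  # word offset of each sentence start
    for (i in seq_len(nrow(a$mentions))) {
      m_sent <- a$mentions$sentence[i]
      if (a$mentions$in_title[i]) {
        p <- 0L
      } else if (unit == "words") {
        if (abs_len == 0L) next
        w <- starts[m_sent + 1L] + a$mentions$token_offset[i] - 1L
        p <- min(floor(w / abs_len * n_parts), n_parts - 1L) + 1L
      } else {
        if (n_sent == 0L) next
        p <- min(floor(m_sent / n_sent * n_parts), n_parts - 1L) + 1L
      }
      part <- c(part, p)
      lab <- c(lab, a$mentions$entity_id[i] %in% gc)
    }
  }
  if (!any(lab) || all(lab)) {
    stop("need both CAE and non-CAE mentions", call. = FALSE)
  }
  nb <- n_parts + 1L  # TITLE + parts
  n_cae <- tabulate(part[lab] + 1L, nbins = nb)
  n_non <- tabulate(part[!lab] + 1L, nbins = nb)
  n <- n_cae + n_non
  rate <- sum(lab) / length(lab)
  out <- tibble::tibble(bin = 0:n_parts,
                        lower = c(NA, (0:(n_parts - 1L)) / n_parts),
                        upper = c(NA, (1:n_parts) / n_parts),
                        n_cae = n_cae, n_noncae = n_non, n = n,
                        p_cae = n_cae / sum(lab),
                        p_noncae = n_non / sum(!lab),
                        prob_gain = ifelse(n > 0, n_cae / n - rate, NA_real_))
  structure(out, overall_cae_rate = rate,
            indicator = paste0("position_", unit),
            class = c("cae_profile", class(out)))
}

#' Frequency-recency map of predicted CAEs
#'
#' Treats the top-k ranked entities of every article as its predicted CAEs,
#' then plots each entity by how many articles predict it (frequency) and
#' the mean publication year of those articles (recency). Thresholds
#' partition the map into four zones: I frequent/older, II frequent/recent,
#' III infrequent/older, IV infrequent/recent -- zone IV holds entities
#' studied in fewer articles more recently.
#'
#' @param annotated A `cae_annotated_corpus` whose corpus carried
#'   publication years (articles without a year are skipped and counted).
#' @param scorer Scorer name or `cae_ranker` used for prediction.
#' @param stats A `cae_corpus_stats`.
#' @param top_k Number of top-ranked entities treated as CAEs (default 2).
#' @param freq_threshold Articles needed to count as "frequent".
#' @param year_threshold First year counting as "recent".
#' @param features,cfg,seed Passed to [rank_corpus()].
#' @return A `cae_freq_recency` tibble: `entity_id`, `frequency`,
#'   `recency`, `zone`; attributes `thresholds`, `n_skipped`, `predictions`
#'   (tibble article_id / entity_id / pub_year, used by [focused_view()]).
#' @export
build_frequency_recency_map <- function(annotated, scorer, stats,
                                        top_k = 2L, freq_threshold = 100L,
                                        year_threshold = 2012L,
                                        features = NULL,
                                        cfg = scorer_config(), seed = NULL) {
  years <- attr(annotated, "pub_year")
  has_year <- names(annotated)[!is.na(years[names(annotated)])]
  n_skipped <- length(annotated) - length(has_year)
  sub <- structure(annotated[has_year], class = "cae_annotated_corpus")
  attr(sub, "pub_year") <- years[has_year]
  rankings <- rank_corpus(sub, scorer, stats, features = features,
                          cfg = cfg, seed = seed)
  preds <- list()
  for (aid in names(rankings)) {
    r <- rankings[[aid]]
    top <- r$entity_id[r$rank <= top_k]
    if (length(top)) {
      preds[[aid]] <- tibble::tibble(article_id = aid, entity_id = top,
                                     pub_year = years[[aid]])
    }
  }
  preds <- if (length(preds)) dplyr::bind_rows(preds) else
    tibble::tibble(article_id = character(), entity_id = character(),
                   pub_year = integer())
  map <- freq_recency_from_predictions(preds, freq_threshold, year_threshold)
  attr(map, "n_skipped") <- n_skipped
  map
}

freq_recency_from_predictions <- function(preds, freq_threshold,
                                          year_threshold) {
  pts <- preds |>
    dplyr::group_by(.data$entity_id) |>
    dplyr::summarise(frequency = dplyr::n(),
                     recency = mean(.data$pub_year), .groups = "drop") |>
    dplyr::arrange(.data$entity_id)
  frequent <- pts$frequency >= freq_threshold
  recent <- pts$recency >= year_threshold
  pts$zone <- dplyr::case_when(
    frequent & !recent ~ "I",
    frequent & recent ~ "II",
    !frequent & !recent ~ "III",
    TRUE ~ "IV")
  structure(pts,
            thresholds = list(freq_threshold = freq_threshold,
                              year_threshold = year_threshold),
            predictions = preds,
            class = c("cae_freq_recency", class(pts)))
}

#' Focused frequency-recency view around one entity
#'
#' Restricts the map to the articles where the focus entity is a predicted
#' CAE and rebuilds frequency and recency for the entities co-predicted
#' there, excluding the focus entity itself.
#'
#' @param map A `cae_freq_recency` from [build_frequency_recency_map()].
#' @param focus Entity id; must be predicted in at least one article.
#' @return A `cae_freq_recency` over the article subset.
#' @export
focused_view <- function(map, focus) {
  preds <- attr(map, "predictions")
  arts <- unique(preds$article_id[preds$entity_id == focus])
  if (length(arts) == 0L) {
    stop("entity '", focus, "' is never a predicted CAE", call. = FALSE)
  }
  th <- attr(map, "thresholds")
  sub <- preds[preds$article_id %in% arts & preds$entity_id != focus, ]
  out <- freq_recency_from_predictions(sub, th$freq_threshold,
                                       th$year_threshold)
  attr(out, "focus") <- focus
  out
}

#' Jaccard similarity between two article sets
#'
#' Used to compare the article set a system recommends for an entity with
#' the set curators selected: `|A1 n A2| / |A1 u A2|`.
#'
#' @param a1,a2 Character vectors of article ids (union must be non-empty).
#' @return Real in [0, 1]; 1 iff the sets are equal.
#' @export
jaccard_article_sets <- function(a1, a2) {
  a1 <- unique(a1); a2 <- unique(a2)
  u <- union(a1, a2)
  if (length(u) == 0L) stop("both article sets are empty", call. = FALSE)
  length(intersect(a1, a2)) / length(u)
}

#' Write a distribution profile as TSV
#' @param profile A `cae_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot a distribution profile
#'
#' Dashed lines: prevalence probabilities of CAEs and non-CAEs per bin.
#' Solid line: probability gain of finding CAEs.
#'
#' @param profile A `cae_profile`.
#' @return A ggplot object.
#' @export
plot_distribution_profile <- function(profile) {
  df <- as.data.frame(profile)
  df <- df[df$n > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p_cae, colour = "P(CAE)"),
                       linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$p_noncae, colour = "P(NonCAE)"),
                       linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$prob_gain, colour = "ProbGain")) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = paste0(attr(profile, "indicator"), " bin"),
                  y = "probability / gain", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a frequency-recency map
#'
#' @param map A `cae_freq_recency`.
#' @param log_freq Use a log10 frequency axis (default TRUE).
#' @return A ggplot object with threshold lines delimiting zones I-IV.
#' @export
plot_frequency_recency <- function(map, log_freq = TRUE) {
  th <- attr(map, "thresholds")
  p <- ggplot2::ggplot(as.data.frame(map),
                       ggplot2::aes(x = .data$recency, y = .data$frequency,
                                    colour = .data$zone)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = th$year_threshold, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = th$freq_threshold, linetype = "dotted") +
    ggplot2::labs(x = "recency (mean publication year)",
                  y = "frequency (articles)") +
    ggplot2::theme_minimal()
  if (log_freq) p <- p + ggplot2::scale_y_log10()
  p
}
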