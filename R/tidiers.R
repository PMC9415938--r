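# broom-style accessors and ggplot2 autoplot methods for pipeline results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-genome CA assignments
#'
#' @param x A `ca_typing` object.
#' @param ... Unused.
#' @return Long tibble: one row per genome x assigned CA type (non-CA
#'   genomes appear once with `ca_type = NA`).
#' @method tidy ca_typing
#' @export
tidy.ca_typing <- function(x, ...) {
  prof <- x$profiles
  rows <- lapply(seq_len(nrow(prof)), function(i) {
    types <- prof$ca_types[[i]]
    tibble::tibble(
      genome_id = prof$genome_id[[i]],
      organism = prof$organism[[i]],
      photoreceptors = prof$photoreceptors[[i]],
      ca_type = if (length(types)) types else NA_character_)
  })
  dplyr::bind_rows(rows)
}

#' One-row cohort summary
#'
#' @param x A `ca_typing` object.
#' @param ... Unused.
#' @return The [cohort_summary()] tibble.
#' @method glance ca_typing
#' @export
glance.ca_typing <- function(x, ...) x$summary

#' Bar chart of CA-type and photoreceptor counts across the cohort
#'
#' @param object A `ca_typing` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ca_typing
#' @export
autoplot.ca_typing <- function(object, ...) {
  s <- object$summary
  df <- tibble::tibble(
    class = factor(c("CcaS", "RcaE", "RfpA", "CA1", "CA2", "CA3", "CA6",
                     "CA7", "non-CA"),
                   levels = c("CcaS", "RcaE", "RfpA", "CA1", "CA2", "CA3",
                              "CA6", "CA7", "non-CA")),
    kind = rep(c("photoreceptor", "CA type"), c(3, 6)),
    n = c(s$n_ccas, s$n_rcae, s$n_rfpa, s$n_ca1, s$n_ca2, s$n_ca3, s$n_ca6,
          s$n_ca7, s$n_non_ca))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$n,
                                   fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "genomes",
                  title = sprintf("Cohort of %d genomes", s$n_genomes)) +
    ggplot2::theme_minimal()
}

#' Hydropathy profile plot with the transmembrane detection rule
#'
#' @param object A [hydropathy()] profile.
#' @param threshold,tail_len,min_run Detection parameters drawn on the plot
#'   (defaults as in [detect_cterm_tm()]).
#' @param ... Unused.
#' @return A ggplot object; a detected C-terminal transmembrane span is
#'   shaded.
#' @method autoplot ca_hydropathy
#' @export
autoplot.ca_hydropathy <- function(object, threshold = 1.6, tail_len = 60L,
                                   min_run = 15L, ...) {
  tm <- detect_cterm_tm(object, tail_len, threshold, min_run)
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$pos, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "residue (window centre)",
                  y = "mean Kyte-Doolittle hydropathy") +
    ggplot2::theme_minimal()
  if (!is.null(tm))
    p <- p + ggplot2::annotate("rect", xmin = tm[["start"]],
                               xmax = tm[["end"]], ymin = -Inf, ymax = Inf,
                               alpha = 0.2, fill = "red")
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
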