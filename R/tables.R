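#' Crossover spans and gene-conversion tracts from a whole-X study
#'
#' Event tables from a whole-genome-sequencing study of 30 hemizygous X
#' chromatids from single Drosophila melanogaster meioses: 15 crossovers
#' (nine single-CO and three double-CO chromatids) and five noncrossover
#' gene-conversion tracts, each localized between flanking markers.
#' `P1` denotes the w1118 parent and `P2` Canton-S.  One crossover (progeny
#' 2e) could not be localized below 18 kb and is excluded from span
#' statistics by the default `max_localized_span` of [summarize_events()].
#'
#' The conversion table records, per event, the nearest non-converted
#' flanking markers, the outermost converted markers, the converted-marker
#' count, and the minimum (between converted markers) and maximum (between
#' non-converted flanks) tract lengths.
#'
#' @return A data frame in the column layout produced by [detect_events()],
#'   plus cytological `band`, `location` and `gene` annotations.
#' @examples
#' co <- xchrom_co_spans()
#' sum(co$span[co$span <= 10000])  # total localized span, bp
#' @export
xchrom_co_spans <- function() {
  read.delim(system.file("extdata", "xchrom_co_spans.tsv", package = "meiorec"),
             stringsAsFactors = FALSE)
}

#' @rdname xchrom_co_spans
#' @export
xchrom_gc_tracts <- function() {
  read.delim(system.file("extdata", "xchrom_gc_tracts.tsv", package = "meiorec"),
             stringsAsFactors = FALSE)
}
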