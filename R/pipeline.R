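# End-to-end orchestration: preprocess -> map -> blocks -> tails
# (-> cleavage -> target scan), emitting the standard report tables.

#' Pipeline configuration
#'
#' @param reads path to a FASTQ file, a collapsed-library TSV, or an
#'   in-memory collapsed `data.frame`.
#' @param precursor a [hairpin()], or a path readable by [read_hairpin()].
#' @param blocks blocks `data.frame` (see [assign_block()]); when `NULL`
#'   and `region_hints` is given, representatives are selected from the data.
#' @param region_hints optional region hints for [select_representatives()].
#' @param b3plus optional B3+ rule.
#' @param filter a [filter_config()]; `NULL` skips read filtering (input
#'   already clean/collapsed).
#' @param race optional RACE fragments (character vector or `data.frame`)
#'   mapped onto `race_reference`.
#' @param race_reference reference for RACE mapping (defaults to the
#'   precursor sequence).
#' @param smallrna,transcripts optional guide + transcripts for
#'   [scan_targets()].
#' @param outdir output directory for the report TSVs.
#' @param seed integer seed recorded in the run log.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(reads, precursor, blocks = NULL,
                            region_hints = NULL, b3plus = NULL,
                            filter = NULL, race = NULL,
                            race_reference = NULL, smallrna = NULL,
                            transcripts = NULL, outdir = tempfile("amirtrace_"),
                            seed = 1L) {
  structure(list(reads = reads, precursor = precursor, blocks = blocks,
                 region_hints = region_hints, b3plus = b3plus,
                 filter = filter, race = race,
                 race_reference = race_reference, smallrna = smallrna,
                 transcripts = transcripts, outdir = outdir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full processing-fidelity pipeline
#'
#' Stages: (1) read loading/filtering/collapsing, (2) exact precursor
#' mapping and size distribution, (3) block assignment and proportions,
#' (4) tailed-variant decomposition, composition and tabulation, and
#' optionally (5) RACE cleavage-site mapping and (6) target scanning.
#' Every report number equals the corresponding module output; a stage
#' failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the per-stage results; report TSVs and a
#'   `run_info.txt` log are written under `config$outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  hp <- stage("precursor", {
    if (inherits(config$precursor, "hairpin")) config$precursor
    else read_hairpin(config$precursor)
  })

  collapsed <- stage("preprocess", {
    reads <- config$reads
    if (is.character(reads)) {
      reads <- if (grepl("\\.f(ast)?q$", reads, ignore.case = TRUE)) {
        read_fastq(reads)
      } else {
        read_collapsed(reads)
      }
    }
    if (!is.null(config$filter) && !("count" %in% names(reads))) {
      reads <- filter_reads(reads, config$filter)$kept
    }
    lib <- collapse_reads(reads)
    if (!is.null(config$filter)) {
      lib <- abundance_filter(lib, config$filter$min_reads)
    }
    lib
  })
  sizes <- size_distribution(collapsed)
  write_table(data.frame(length = as.integer(names(sizes)),
                         reads = as.integer(sizes)),
              file.path(config$outdir, "size_distribution.tsv"))

  mapped <- stage("map", map_exact(collapsed, hp))
  write_table(mapped, file.path(config$outdir, "precursor_hits.tsv"))

  blocks <- config$blocks
  if (is.null(blocks) && !is.null(config$region_hints)) {
    blocks <- stage("blocks", select_representatives(mapped, config$region_hints))
  }
  assignments <- proportions <- NULL
  if (!is.null(blocks)) {
    write_table(blocks, file.path(config$outdir, "blocks.tsv"))
    if (nrow(mapped) > 0L) {
      assignments <- stage("blocks", assign_block(mapped, blocks, config$b3plus))
      write_table(assignments, file.path(config$outdir, "assignments.tsv"))
      if (any(assignments$block != "unassigned")) {
        proportions <- stage("blocks", block_proportions(assignments))
        write_table(proportions, file.path(config$outdir, "proportions.tsv"))
      }
    }
  }

  unmapped <- collapsed[!collapsed$sequence %in% mapped$sequence, ,
                        drop = FALSE]
  tails <- stage("tails", decompose_tail(unmapped, hp, blocks = blocks,
                                         b3plus = config$b3plus))
  if (nrow(tails$variants)) {
    tab <- if (!is.null(blocks) && !anyNA(tails$variants$block)) {
      tabulate_tailed(tails$variants)
    } else {
      data.frame(sequence = paste0(tolower(tails$variants$gmc),
                                   toupper(tails$variants$tail)),
                 reads = tails$variants$count,
                 block = tails$variants$block, stringsAsFactors = FALSE)
    }
    write_table(tab, file.path(config$outdir, "tailed_variants.tsv"))
    comp <- tail_composition(tails$variants)
    write_table(data.frame(nucleotide = names(comp), percent = unname(comp)),
                file.path(config$outdir, "tail_composition.tsv"))
  }

  cleavage <- NULL
  if (!is.null(config$race)) {
    ref <- config$race_reference
    if (is.null(ref)) ref <- setNames(hp$sequence, hp$name)
    cleavage <- stage("cleavage", map_5p_ends(config$race, ref))
    write_table(cleavage$sites, file.path(config$outdir, "cleavage_sites.tsv"))
  }

  scan <- NULL
  if (!is.null(config$smallrna) && !is.null(config$transcripts)) {
    scan <- stage("scan", scan_targets(config$smallrna, config$transcripts))
    write_table(scan, file.path(config$outdir, "scan_hits.tsv"))
  }

  writeLines(c(paste0("amiRtrace ",
                      as.character(utils::packageVersion("amiRtrace"))),
               paste0("seed: ", config$seed),
               paste0("precursor: ", hp$name),
               paste0("reads: ", sum(collapsed$count),
                      " (", nrow(collapsed), " unique)")),
             file.path(config$outdir, "run_info.txt"))

  invisible(list(collapsed = collapsed, sizes = sizes, mapped = mapped,
                 blocks = blocks, assignments = assignments,
                 proportions = proportions, tails = tails,
                 cleavage = cleavage, scan = scan, outdir = config$outdir))
}
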