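#' Run the full analysis pipeline
#'
#' Executes whichever stages the configuration provides inputs for and
#' assembles one report bundle: the inheritance-model hierarchy for a
#' progeny count table, pairwise Kolmogorov-Smirnov comparisons plus
#' normality tests and the maximum-dispersal order-statistic report for a
#' distance table, germination rates and timeline for plating records, and
#' a chi-squared independence test for a contingency table. Stage failures
#' are isolated: a failing stage is reported in `$errors` and the others
#' still run.
#'
#' @param counts Path to a cross-counts file, or `NULL` to skip.
#' @param distances Path to a per-colony distance file, or `NULL`.
#' @param germination Path to a germination plate file, or `NULL`.
#' @param contingency Path to a contingency-table file, or `NULL`.
#' @param design Optional path to a design override file.
#' @param tol,max_iter IRLS settings for the hierarchy stage.
#' @param ks_method KS p-value method (`"auto"`, `"exact"`, `"asymptotic"`).
#' @param n_ranks Order-statistic count for the maximum-dispersal test.
#' @param out Optional output prefix; when given, delimited and JSON
#'   reports are written.
#' @return List of class `pipeline_result` with elements `hierarchy`,
#'   `dispersal`, `germination`, `association` (stages not requested are
#'   `NULL`), and `errors`.
#' @export
#' @examples
#' res <- run_pipeline(counts = system.file("extdata", "f2_progeny_counts.csv",
#'                                          package = "conidiomorph"))
#' res$hierarchy
run_pipeline <- function(counts = NULL, distances = NULL, germination = NULL,
                         contingency = NULL, design = NULL,
                         tol = 1e-8, max_iter = 100L,
                         ks_method = "auto", n_ranks = 3L, out = NULL) {
  errors <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  dsg <- if (is.null(design)) default_design() else read_design(design)

  hierarchy <- if (!is.null(counts)) {
    run_stage("hierarchy", hierarchy_table(read_counts(counts), dsg,
                                           tol = tol, max_iter = max_iter))
  }

  dispersal <- if (!is.null(distances)) {
    run_stage("dispersal", {
      df <- read_distances(distances)
      groups <- split(df$distance_cm, df$phenotype)
      groups <- groups[intersect(phenotype_levels(), names(groups))]
      pairs <- utils::combn(names(groups), 2L, simplify = FALSE)
      ks <- do.call(rbind, lapply(pairs, function(pr) {
        r <- ks_test(groups[[pr[1L]]], groups[[pr[2L]]], method = ks_method)
        data.frame(sample_a = pr[1L], sample_b = pr[2L],
                   d = r$d_statistic, p = r$p_value, method = r$method,
                   n1 = r$n1, n2 = r$n2)
      }))
      normality <- do.call(rbind, lapply(names(groups), function(g) {
        if (length(groups[[g]]) < 3) return(NULL)
        sw <- shapiro_wilk(groups[[g]])
        data.frame(phenotype = g, w = sw$w_statistic, p = sw$p_value,
                   n = sw$n)
      }))
      # maxima standardized against the pooled movement of all colonies
      pooled <- unlist(groups, use.names = FALSE)
      maxima <- do.call(rbind, lapply(names(groups), function(g) {
        mx <- max_dispersal_test(max(groups[[g]]), mean(pooled),
                                 stats::var(pooled), n_ranks = n_ranks)
        data.frame(phenotype = g, max_cm = mx$max_distance, z = mx$z,
                   z_squared = mx$z_squared,
                   chisq1_tail = mx$chisq1_tail,
                   largest_rank_tail = mx$largest_rank_tail)
      }))
      list(ks = ks, normality = normality, maxima = maxima)
    })
  }

  germ <- if (!is.null(germination)) {
    run_stage("germination", {
      df <- read_germination(germination)
      df$rate_pct <- vapply(seq_len(nrow(df)), function(i) {
        germination_rate(unlist(df[i, c("rep1", "rep2", "rep3")]),
                         df$expected[i])
      }, numeric(1L))
      timeline <- germination_timeline(df)
      list(rates = df[, c("strain", "phenotype", "condition", "rate_pct")],
           timeline = timeline)
    })
  }

  assoc <- if (!is.null(contingency)) {
    run_stage("association", association_test(read_contingency(contingency)))
  }

  result <- structure(list(hierarchy = hierarchy, dispersal = dispersal,
                           germination = germ, association = assoc,
                           errors = errors),
                      class = "pipeline_result")
  if (!is.null(out)) write_pipeline(result, out)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  ran <- names(Filter(Negate(is.null),
                      x[c("hierarchy", "dispersal", "germination", "association")]))
  cat("Pipeline stages run:", if (length(ran)) paste(ran, collapse = ", ")
      else "none", "\n")
  if (length(x$errors)) {
    cat("Stage errors:\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[[nm]], "\n", sep = "")
  }
  for (nm in ran) {
    cat("\n== ", nm, " ==\n", sep = "")
    obj <- x[[nm]]
    if (inherits(obj, "hierarchy_report") ||
        inherits(obj, "association_result")) {
      print(obj)
    } else if (nm == "dispersal") {
      print(obj$ks, row.names = FALSE)
    } else if (nm == "germination") {
      print(obj$rates, row.names = FALSE)
    }
  }
  invisible(x)
}

#' Write a pipeline result bundle to disk
#'
#' Emits one JSON summary (`<prefix>_summary.json`, full precision) plus
#' delimited tables for the stages that ran.
#'
#' @param result A `pipeline_result`.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_pipeline <- function(result, prefix) {
  paths <- character()
  if (!is.null(result$hierarchy)) {
    paths <- c(paths, write_hierarchy_report(result$hierarchy, prefix))
  }
  if (!is.null(result$dispersal)) {
    p <- paste0(prefix, "_ks.csv")
    utils::write.csv(result$dispersal$ks, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
    p <- paste0(prefix, "_maxima.csv")
    utils::write.csv(result$dispersal$maxima, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(result$germination)) {
    p <- paste0(prefix, "_germination.csv")
    utils::write.csv(result$germination$rates, p, row.names = FALSE,
                     quote = FALSE)
    paths <- c(paths, p)
  }
  summary <- list(
    hierarchy = if (!is.null(result$hierarchy)) {
      list(table = as.data.frame(result$hierarchy),
           heritability = {
             h2 <- attr(result$hierarchy, "heritability")
             if (is.null(h2)) NULL else unclass(h2)
           })
    },
    dispersal = result$dispersal,
    germination = if (!is.null(result$germination)) {
      list(rates = result$germination$rates,
           days = {
             tl <- result$germination$timeline
             as.data.frame(as.table(tl$days), stringsAsFactors = FALSE)
           },
           earliest = result$germination$timeline$earliest)
    },
    association = if (!is.null(result$association)) {
      r <- result$association
      list(chisq = r$chisq, df = r$df, p_value = r$p_value)
    },
    errors = result$errors
  )
  p <- paste0(prefix, "_summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, force = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
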