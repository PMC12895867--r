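# Thromboembolic events are identified by matching reaction Preferred
# Terms (PTs) against user-supplied PT lists: three disjoint top-level
# categories (VTE, ATE, unspecified_mixed) mirroring the embolic and
# thrombotic events SMQ, plus nested subtypes (PE within VTE; MI and
# cerebral_ATE within ATE). MedDRA itself is licensed, so PT membership is
# configuration; a small synthetic dictionary ships for tests and examples.

TEE_CATEGORIES <- c("VTE", "ATE", "unspecified_mixed")
TEE_SUBTYPES <- c(PE = "VTE", MI = "ATE", cerebral_ATE = "ATE")
OVERALL_LABEL <- "overall_TEE"

#' Load an event dictionary from YAML config or a list
#'
#' PTs are upper-cased and trimmed; structural invariants are enforced:
#' each subtype must be contained in its parent category, and the top-level
#' categories must be pairwise disjoint. The overall TEE set is derived as
#' the union of the three categories, never stored.
#'
#' @param config path to a YAML file, or an equivalent named list with
#'   elements `categories` (named lists of PTs for `VTE`, `ATE`,
#'   `unspecified_mixed`), `subtypes` (`PE`, `MI`, `cerebral_ATE`) and
#'   optionally `smq_id`
#' @return object of class `event_dictionary`
#' @export
load_event_dictionary <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  norm <- function(x) unique(toupper(trimws(as.character(unlist(x %||% character())))))
  cats <- lapply(setNames(TEE_CATEGORIES, TEE_CATEGORIES),
                 function(k) norm(config$categories[[k]]))
  subs <- lapply(setNames(names(TEE_SUBTYPES), names(TEE_SUBTYPES)),
                 function(k) norm(config$subtypes[[k]]))

  for (i in seq_along(TEE_CATEGORIES)) {
    for (j in seq_len(i - 1L)) {
      dup <- intersect(cats[[i]], cats[[j]])
      if (length(dup)) {
        stop(sprintf("PT '%s' appears in both %s and %s", dup[[1L]],
                     TEE_CATEGORIES[[j]], TEE_CATEGORIES[[i]]))
      }
    }
  }
  for (s in names(TEE_SUBTYPES)) {
    parent <- TEE_SUBTYPES[[s]]
    stray <- setdiff(subs[[s]], cats[[parent]])
    if (length(stray)) {
      stop(sprintf("subtype %s PT '%s' is not contained in parent category %s",
                   s, stray[[1L]], parent))
    }
  }

  structure(list(categories = cats, subtypes = subs,
                 smq_id = as.character(config$smq_id %||% "")),
            class = "event_dictionary")
}

#' @export
print.event_dictionary <- function(x, ...) {
  cat(sprintf("<event_dictionary> %d PTs (%s)\n",
              length(dictionary_pts(x)),
              paste(sprintf("%s:%d", names(x$categories),
                            lengths(x$categories)), collapse = " ")))
  invisible(x)
}

#' All PTs of a dictionary, optionally restricted to one label
#' @param dict `event_dictionary`
#' @param label a category, subtype, or `"overall_TEE"` (default: overall)
#' @return character vector of PTs
#' @export
dictionary_pts <- function(dict, label = OVERALL_LABEL) {
  if (label == OVERALL_LABEL) return(unique(unlist(dict$categories, use.names = FALSE)))
  sets <- c(dict$categories, dict$subtypes)
  if (!label %in% names(sets)) stop("unknown event label: ", label)
  sets[[label]]
}

#' Event labels of a dictionary (categories, subtypes, overall)
#' @param dict `event_dictionary`
#' @return character vector
#' @export
dictionary_labels <- function(dict) {
  c(TEE_CATEGORIES, names(TEE_SUBTYPES), OVERALL_LABEL)
}

#' Classify one set of reaction PTs
#'
#' A label is assigned iff the PT set intersects that label's PT list;
#' `overall_TEE` is assigned iff any top-level category is. Each label is
#' assigned at most once however many PTs match.
#'
#' @param pts character vector of reaction PTs (case-insensitive)
#' @param dict `event_dictionary`
#' @return character vector of labels (possibly empty)
#' @export
classify_pts <- function(pts, dict) {
  pts <- unique(toupper(trimws(pts)))
  sets <- c(dict$categories, dict$subtypes)
  hit <- names(sets)[vapply(sets, function(s) any(pts %in% s), logical(1))]
  if (any(hit %in% TEE_CATEGORIES)) hit <- c(hit, OVERALL_LABEL)
  # stable order: categories, subtypes, overall
  intersect(c(TEE_CATEGORIES, names(TEE_SUBTYPES), OVERALL_LABEL), hit)
}

#' Classify every report in a collection
#'
#' @param reports `faers_reports` object (or a data.table with columns
#'   `primaryid`, `pt`)
#' @param dict `event_dictionary`
#' @return data.table `(primaryid, label)`, one row per distinct
#'   report-label pair — counts per label are counts of distinct reports
#' @export
classify_reports <- function(reports, dict) {
  reac <- if (inherits(reports, "faers_reports")) reports$reac else reports
  sets <- c(dict$categories, dict$subtypes)
  pieces <- lapply(names(sets), function(lab) {
    ids <- unique(reac$primaryid[reac$pt %in% sets[[lab]]])
    if (length(ids)) data.table::data.table(primaryid = ids, label = lab)
  })
  out <- data.table::rbindlist(pieces)
  if (nrow(out) == 0L) {
    return(data.table::data.table(primaryid = character(), label = character()))
  }
  overall <- unique(out[label %in% TEE_CATEGORIES, .(primaryid)])
  overall[, label := OVERALL_LABEL]
  rbind(out, overall)[order(primaryid, label)]
}

#' Path to the bundled synthetic example dictionary
#'
#' A small illustrative PT dictionary for tests and examples; real-data
#' analyses require the user's own MedDRA-derived PT lists.
#'
#' @return file path
#' @export
example_dictionary_path <- function() {
  system.file("extdata", "tee_dictionary_synthetic.yaml",
              package = "faerstee", mustWork = TRUE)
}
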