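# Text-label construction, storage, and embedding.
#
# Labels pair each image file name with a natural-language caption built
# from three descriptor axes: vessel density (sparse/moderate/dense), vessel
# distribution (radial/reticular/mixed), and a possibly empty list of
# abnormal-area descriptors. Tables are stored as CSV (canonical) or xlsx.
# The text encoder interface has two backends: an offline deterministic stub
# (seeded hash per token) and a pretrained-transformer hook that errors
# loudly when no backend is registered — never a silent fallback.

DENSITY_CLASSES <- c("sparse", "moderate", "dense")
DISTRIBUTION_CLASSES <- c("radial", "reticular", "mixed")

#' Load caption templates
#' @param path YAML template file; defaults to the file shipped with the
#'   package.
#' @return nested list with `density`, `distribution` and `abnormal` entries.
#' @export
caption_templates <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("templates", "captions.yaml", package = "vesselvit")
  }
  tpl <- yaml::read_yaml(path)
  stopifnot(all(DENSITY_CLASSES %in% names(tpl$density)),
            all(DISTRIBUTION_CLASSES %in% names(tpl$distribution)))
  tpl
}

#' Generate a caption from structured descriptors
#'
#' Assembles one sentence per descriptor axis; each nonempty descriptor is
#' mentioned exactly once. Deterministic: identical inputs give identical
#' strings.
#'
#' @param density_class one of `"sparse"`, `"moderate"`, `"dense"`.
#' @param distribution_class one of `"radial"`, `"reticular"`, `"mixed"`.
#' @param abnormal_areas character vector of region descriptors (may be
#'   empty), e.g. `"upper left"`.
#' @param templates a [caption_templates()] list.
#' @return a single caption string.
#' @export
#' @examples
#' generate_caption("dense", "radial", character(0))
generate_caption <- function(density_class, distribution_class,
                             abnormal_areas = character(0),
                             templates = caption_templates()) {
  if (!density_class %in% DENSITY_CLASSES) {
    stop("unknown density class: ", density_class, call. = FALSE)
  }
  if (!distribution_class %in% DISTRIBUTION_CLASSES) {
    stop("unknown distribution class: ", distribution_class, call. = FALSE)
  }
  parts <- c(templates$density[[density_class]],
             templates$distribution[[distribution_class]])
  for (region in abnormal_areas) {
    parts <- c(parts, gsub("{region}", region, templates$abnormal,
                           fixed = TRUE))
  }
  paste(parts[nzchar(parts)], collapse = " ")
}

#' Construct a text label
#' @param image_id image file name (non-empty).
#' @param density_class,distribution_class,abnormal_areas descriptors, see
#'   [generate_caption()].
#' @param caption optional explicit caption; generated from the descriptors
#'   when omitted.
#' @return object of class `text_label`.
#' @export
text_label <- function(image_id, density_class, distribution_class,
                       abnormal_areas = character(0), caption = NULL) {
  stopifnot(nzchar(image_id))
  if (is.null(caption)) {
    caption <- generate_caption(density_class, distribution_class,
                                abnormal_areas)
  }
  stopifnot(nzchar(caption))
  structure(list(image_id = image_id, caption = caption,
                 density_class = density_class,
                 distribution_class = distribution_class,
                 abnormal_areas = abnormal_areas),
            class = "text_label")
}

LABEL_COLUMNS <- c("image_id", "caption", "density_class",
                   "distribution_class", "abnormal_areas")

#' Build a label table from text labels
#' @param labels list of [text_label()] objects.
#' @return `label_table`: a data.frame with one row per image, columns
#'   image_id, caption, density_class, distribution_class, abnormal_areas
#'   (semicolon-joined).
#' @export
label_table <- function(labels) {
  df <- data.frame(
    image_id = vapply(labels, `[[`, character(1), "image_id"),
    caption = vapply(labels, `[[`, character(1), "caption"),
    density_class = vapply(labels, `[[`, character(1), "density_class"),
    distribution_class = vapply(labels, `[[`, character(1),
                                "distribution_class"),
    abnormal_areas = vapply(labels, function(l)
      paste(l$abnormal_areas, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  validate_label_table(df)
}

validate_label_table <- function(df) {
  missing <- setdiff(LABEL_COLUMNS, names(df))
  if (length(missing)) {
    stop("label table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$image_id)) {
    stop("duplicate image_id in label table: ",
         paste(unique(df$image_id[duplicated(df$image_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(df$image_id)) || any(!nzchar(df$caption))) {
    stop("image_id and caption must be non-empty", call. = FALSE)
  }
  df <- df[, LABEL_COLUMNS]
  class(df) <- c("label_table", "data.frame")
  df
}

#' Read a label table from CSV or xlsx
#'
#' @param path file path.
#' @param dialect `"csv"` or `"xlsx"`; guessed from the extension when
#'   omitted. Reading xlsx requires the `readxl` package.
#' @return a validated `label_table`.
#' @export
read_label_table <- function(path, dialect = c("auto", "csv", "xlsx")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (tolower(tools::file_ext(path)) == "xlsx") "xlsx" else "csv"
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "csv") {
    if (file.size(path) == 0) {
      stop("empty label table file: ", path, call. = FALSE)
    }
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  } else {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the 'readxl' package", call. = FALSE)
    }
    df <- as.data.frame(readxl::read_excel(path, col_types = "text"),
                        stringsAsFactors = FALSE)
    df[is.na(df)] <- ""
  }
  if (nrow(df) == 0 && ncol(df) == 0) {
    stop("label table file has no content: ", path, call. = FALSE)
  }
  validate_label_table(df)
}

#' Write a label table to CSV or xlsx
#' @param table a `label_table` (or conforming data.frame).
#' @param path output path.
#' @param dialect `"csv"` or `"xlsx"`; guessed from the extension when
#'   omitted.
#' @export
write_label_table <- function(table, path, dialect = c("auto", "csv", "xlsx")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (tolower(tools::file_ext(path)) == "xlsx") "xlsx" else "csv"
  }
  table <- validate_label_table(as.data.frame(table))
  if (dialect == "csv") {
    utils::write.csv(table, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  } else {
    df <- as.data.frame(lapply(table, as.character),
                        stringsAsFactors = FALSE)
    write_minimal_xlsx(df, path)
  }
  invisible(path)
}

#' Embed a caption as a token-embedding matrix
#'
#' The `stub` backend is fully offline and deterministic: the caption is
#' whitespace-tokenized, truncated to `max_tokens`, and every token is mapped
#' to a fixed `d_text`-dimensional vector drawn from an RNG seeded by a hash
#' of (token, seed, d_text) — independent of call order and of the global
#' RNG state. The `pretrained` backend delegates to a function registered as
#' `options(vesselvit.pretrained_embedder = function(caption, max_tokens))`
#' and errors when none is available.
#'
#' @param caption non-empty string.
#' @param embedder `"stub"` or `"pretrained"`.
#' @param max_tokens truncation length (default 32).
#' @param d_text embedding dimension (default 768, BERT-base convention).
#' @param seed integer stub seed.
#' @return (T, d_text) matrix, T <= max_tokens.
#' @export
embed_text <- function(caption, embedder = c("stub", "pretrained"),
                       max_tokens = 32L, d_text = 768L, seed = 0L) {
  embedder <- match.arg(embedder)
  if (!is.character(caption) || length(caption) != 1L || !nzchar(caption)) {
    stop("caption must be a non-empty string", call. = FALSE)
  }
  if (embedder == "pretrained") {
    fn <- getOption("vesselvit.pretrained_embedder")
    if (is.null(fn)) {
      stop("pretrained text embedder backend is not available; register one ",
           "via options(vesselvit.pretrained_embedder = ...) or use the ",
           "'stub' embedder", call. = FALSE)
    }
    return(fn(caption, max_tokens))
  }
  tokens <- strsplit(trimws(caption), "\\s+")[[1]]
  tokens <- tokens[seq_len(min(length(tokens), max_tokens))]
  out <- matrix(0, length(tokens), d_text)
  for (i in seq_along(tokens)) {
    out[i, ] <- stub_token_embedding(tokens[i], seed, d_text)
  }
  out
}

# deterministic per-token embedding; leaves the global RNG untouched
stub_token_embedding <- function(token, seed, d_text) {
  key <- paste(token, seed, d_text, sep = "\r")
  h <- digest::digest(key, algo = "xxhash32", serialize = FALSE)
  token_seed <- strtoi(substr(h, 1, 7), 16L)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(token_seed)
  stats::rnorm(d_text) / sqrt(d_text)
}
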