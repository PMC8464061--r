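#' Read an expression matrix
#'
#' Supported on-disk layouts: delimited text (TSV/CSV, feature rows, first
#' column feature ids, header of observation ids) and a MatrixMarket triplet
#' (`matrix.mtx` with `features.tsv`/`genes.tsv` and `barcodes.tsv`
#' companions in the same directory). Triplet orientation is auto-detected
#' from the companion file lengths and transposed to features x observations
#' when needed.
#'
#' @param path File path (for `"mtx"`, the `.mtx` file).
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"`, or `"mtx"`.
#' @return Dense numeric matrix, features x observations.
#' @export
read_matrix <- function(path, format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      mtx = "mtx",
      csv = "csv",
      "tsv"
    )
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "mtx") {
    return(read_mtx_triplet(path))
  }
  if (file.size(path) == 0) {
    stop("failed to parse ", path, ": file is empty", call. = FALSE)
  }
  sep <- if (format == "csv") "," else "\t"
  dt <- tryCatch(
    withCallingHandlers(
      data.table::fread(
        file = path, sep = sep, header = TRUE,
        data.table = FALSE, fill = FALSE
      ),
      # housekeeping notice after a previous fread abort; not a parse problem
      warning = function(w) {
        if (grepl("cleaned up", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    ),
    error = function(e) {
      stop("failed to parse ", path, ": ", conditionMessage(e), call. = FALSE)
    },
    warning = function(w) {
      stop("failed to parse ", path, ": ", conditionMessage(w), call. = FALSE)
    }
  )
  if (nrow(dt) == 0L || ncol(dt) < 2L) {
    stop("failed to parse ", path, ": no data rows/columns", call. = FALSE)
  }
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate feature ids in ", path, ": ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  vals <- dt[, -1L, drop = FALSE]
  nonnum <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(nonnum)) {
    stop("non-numeric columns in ", path, ": ",
      paste(nonnum, collapse = ", "),
      call. = FALSE
    )
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  validate_matrix(m)
  m
}

read_mtx_triplet <- function(path) {
  dir <- dirname(path)
  feat_path <- Filter(file.exists, file.path(dir, c("features.tsv", "genes.tsv")))
  bc_path <- file.path(dir, "barcodes.tsv")
  if (length(feat_path) == 0L || !file.exists(bc_path)) {
    stop("MTX triplet requires features.tsv (or genes.tsv) and barcodes.tsv alongside ",
      path,
      call. = FALSE
    )
  }
  read_ids <- function(p) {
    vapply(strsplit(readLines(p), "\t", fixed = TRUE), `[[`, character(1), 1L)
  }
  features <- read_ids(feat_path[[1L]])
  barcodes <- read_ids(bc_path)
  mm <- as.matrix(Matrix::readMM(path))
  if (nrow(mm) == length(features) && ncol(mm) == length(barcodes)) {
    if (nrow(mm) == ncol(mm)) message("square MTX: assuming feature rows")
  } else if (nrow(mm) == length(barcodes) && ncol(mm) == length(features)) {
    message("MTX stored observations x features; transposing")
    mm <- t(mm)
  } else {
    stop("MTX dimensions match neither companion-file orientation", call. = FALSE)
  }
  dimnames(mm) <- list(features, barcodes)
  validate_matrix(mm)
  mm
}

#' Write an expression matrix as delimited text
#'
#' @param x Numeric matrix, features x observations.
#' @param path Output path.
#' @param sep Field separator (tab default).
#' @export
write_matrix <- function(x, path, sep = "\t") {
  validate_matrix(x)
  df <- data.frame(feature = rownames(x), x, check.names = FALSE)
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}

#' Read observation group labels from a two-column TSV
#'
#' @param path Path to a TSV with observation id and group label columns
#'   (a header row starting with `observation` is skipped).
#' @return Named character vector, observation id -> group label.
#' @export
read_group_labels <- function(path) {
  dt <- utils::read.delim(path,
    header = FALSE, sep = "\t",
    colClasses = "character"
  )
  if (ncol(dt) < 2L) stop("group file must have two columns", call. = FALSE)
  if (tolower(dt[1L, 1L]) %in% c("observation", "observation_id")) {
    dt <- dt[-1L, , drop = FALSE]
  }
  setNames(as.character(dt[[2L]]), as.character(dt[[1L]]))
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member features.
#'
#' @param path Path to the `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) stop("malformed GMT line: ", f[1L], call. = FALSE)
    f[-(1:2)]
  })
  names(sets) <- vapply(
    strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L
  )
  sets
}

#' Read a phenotype table with a declared type row
#'
#' Layout: a header row (`observation` then variable names), a type row
#' whose first field is `#type` declaring `continuous` or `categorical` per
#' variable, then one row per observation.
#'
#' @param path Path to the TSV.
#' @return List with `data` (data frame, observation row names) and `types`
#'   (named character vector).
#' @export
read_phenotypes <- function(path) {
  dt <- utils::read.delim(path,
    header = TRUE, sep = "\t",
    colClasses = "character", check.names = FALSE
  )
  if (nrow(dt) < 2L || dt[1L, 1L] != "#type") {
    stop("phenotype table must have a '#type' row after the header", call. = FALSE)
  }
  types <- setNames(as.character(dt[1L, -1L]), names(dt)[-1L])
  bad <- types[!types %in% c("continuous", "categorical")]
  if (length(bad)) {
    stop("unknown phenotype types: ", paste(unique(bad), collapse = ", "),
      call. = FALSE
    )
  }
  data <- dt[-1L, , drop = FALSE]
  rownames(data) <- data[[1L]]
  data <- data[, -1L, drop = FALSE]
  for (v in names(types)) {
    if (types[[v]] == "continuous") data[[v]] <- as.numeric(data[[v]])
  }
  list(data = data, types = types)
}

# Serializable view of a taxonomy (drops the function-valued plug-in).
taxonomy_payload <- function(tax) {
  nodes <- tax$nodes
  cfg <- unclass(tax$config)
  cfg$custom_partitioner <- NULL
  list(
    mode = tax$mode,
    config = cfg,
    items = as.list(tax$items),
    groups = if (is.null(tax$groups)) NULL else as.list(tax$groups),
    nodes = lapply(seq_len(nrow(nodes)), function(i) {
      list(
        node_id = nodes$node_id[i],
        parent = nodes$parent[i],
        depth = nodes$depth[i],
        m = nodes$m[i],
        items = as.list(nodes$items[[i]]),
        n_items = nodes$n_items[i],
        is_leaf = nodes$is_leaf[i],
        ps = nodes$ps[i],
        height = nodes$height[i],
        stop_reason = nodes$stop_reason[i],
        children = if (is.null(nodes$children[[i]])) NULL else as.list(nodes$children[[i]]),
        seed = nodes$seed[i]
      )
    })
  )
}

newick_label <- function(x) gsub("[ ,():;\\[\\]']", "_", x)

# Newick with branch length = parent height - child height (root gets 0).
taxonomy_newick <- function(tax) {
  nodes <- tax$nodes
  build <- function(id, parent_h) {
    i <- match(id, nodes$node_id)
    bl <- if (is.na(parent_h)) 0 else parent_h - nodes$height[i]
    if (!is.na(parent_h) && bl < 0) {
      stop("internal error: negative branch length at ", id, call. = FALSE)
    }
    if (nodes$is_leaf[i]) {
      label <- if (nodes$n_items[i] == 1L) nodes$items[[i]] else nodes$node_id[i]
      sprintf("%s:%.10g", newick_label(label), bl)
    } else {
      kids <- nodes$children[[i]]
      sprintf(
        "(%s,%s)%s:%.10g",
        build(kids[1L], nodes$height[i]),
        build(kids[2L], nodes$height[i]),
        newick_label(id), bl
      )
    }
  }
  paste0(build(nodes$node_id[is.na(nodes$parent)], NA_real_), ";")
}

#' Write a fitted taxonomy to a directory
#'
#' Writes `taxonomy.json` (the canonical, lossless serialization: full node
#' records with stabilities, heights, seeds and stop reasons) and
#' `taxonomy.nwk` (derived Newick; branch lengths are parent height minus
#' child height).
#'
#' @param tax A `k2_taxonomy` with heights computed.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_taxonomy <- function(tax, dir) {
  stopifnot(inherits(tax, "k2_taxonomy"))
  if (any(is.na(tax$nodes$height))) stop("heights not computed", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "taxonomy.json")
  nwk_path <- file.path(dir, "taxonomy.nwk")
  json <- jsonlite::toJSON(taxonomy_payload(tax),
    auto_unbox = TRUE, digits = I(17), pretty = TRUE, null = "null", na = "null"
  )
  writeLines(json, json_path)
  writeLines(taxonomy_newick(tax), nwk_path)
  invisible(c(json = json_path, newick = nwk_path))
}

#' Read a taxonomy back from its JSON serialization
#'
#' @param path Path to a `taxonomy.json` written by [write_taxonomy()].
#' @return A `k2_taxonomy`.
#' @export
read_taxonomy <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  nodes <- dplyr::bind_rows(lapply(obj$nodes, function(n) {
    tibble(
      node_id = n$node_id,
      parent = if (is.null(n$parent)) NA_character_ else n$parent,
      depth = as.integer(n$depth),
      m = if (is.null(n$m)) NA_integer_ else as.integer(n$m),
      items = list(unlist(n$items)),
      n_items = as.integer(n$n_items),
      is_leaf = isTRUE(n$is_leaf),
      ps = if (is.null(n$ps)) NA_real_ else as.numeric(n$ps),
      height = as.numeric(n$height),
      stop_reason = if (is.null(n$stop_reason)) NA_character_ else n$stop_reason,
      children = list(if (is.null(n$children)) NULL else unlist(n$children)),
      seed = as.integer(n$seed)
    )
  }))
  cfg_args <- obj$config
  cfg <- do.call(taxonomy_config, cfg_args)
  structure(
    list(
      nodes = nodes, mode = obj$mode, config = cfg,
      groups = if (is.null(obj$groups)) NULL else unlist(obj$groups),
      items = unlist(obj$items)
    ),
    class = c("k2_taxonomy", "k2_tree")
  )
}
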