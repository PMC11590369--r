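#' Geographic range tables and epoch-wise connectivity
#'
#' A range table codes presence (1) / absence (0) of each taxon over a set
#' of named areas. A connectivity model is a stack of 0/1 area-by-area
#' matrices, one per geological epoch, coding whether dispersal between two
#' areas is possible during that epoch (0 = disconnected, 1 = connected).
#'
#' @param path CSV file. For ranges: first column `taxon`, remaining columns
#'   one per area with 0/1 entries. For connectivity: columns `epoch`,
#'   `start_ma`, `end_ma`, `area`, then one column per area; each epoch block
#'   has one row per source area.
#' @return `read_range_table` returns a tibble of class `range_table` with an
#'   `areas` attribute; `read_connectivity` returns a `connectivity_model`.
#' @export
read_range_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "taxon") names(df)[1] <- "taxon"
  areas <- names(df)[-1]
  if (length(areas) < 1) stop("no area columns found")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!all(m %in% c(0, 1))) stop("range entries must be 0/1")
  if (any(rowSums(m) == 0)) {
    stop(sprintf("all-zero range row for taxon '%s'",
                 df$taxon[which(rowSums(m) == 0)[1]]))
  }
  range_table(df$taxon, m, areas)
}

#' @rdname read_range_table
#' @param taxa Taxon labels.
#' @param presence 0/1 matrix, taxa in rows, areas in columns.
#' @param areas Area codes.
#' @export
range_table <- function(taxa, presence, areas) {
  presence <- as.matrix(presence)
  if (ncol(presence) != length(areas)) stop("presence/areas width mismatch")
  if (any(rowSums(presence) == 0)) stop("every taxon needs >= 1 presence")
  out <- tibble::as_tibble(as.data.frame(presence))
  names(out) <- areas
  out <- dplyr::bind_cols(tibble::tibble(taxon = taxa), out)
  structure(out, areas = areas,
            class = c("range_table", class(out)))
}

#' @rdname read_range_table
#' @param x A `range_table`.
#' @export
write_range_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

range_masks <- function(x) {
  areas <- attr(x, "areas")
  m <- as.matrix(x[, areas])
  stats::setNames(as.integer(m %*% bitwShiftL(1L, seq_along(areas) - 1L)),
                  x$taxon)
}

#' @rdname read_range_table
#' @export
read_connectivity <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("epoch", "start_ma", "end_ma", "area")
  if (!all(need %in% names(df))) {
    stop("connectivity CSV needs columns epoch, start_ma, end_ma, area")
  }
  areas <- setdiff(names(df), need)
  eps <- unique(df[, c("epoch", "start_ma", "end_ma")])
  mats <- lapply(split(df, df$epoch), function(blk) {
    m <- as.matrix(blk[, areas, drop = FALSE])
    rownames(m) <- blk$area
    m <- m[areas, areas, drop = FALSE]
    if (!all(m %in% c(0, 1))) stop("connectivity entries must be 0/1")
    if (!isTRUE(all.equal(m, t(m)))) {
      warning("non-symmetric connectivity matrix kept as directed")
    }
    m
  })
  connectivity_model(mats[as.character(eps$epoch)],
                     eps$start_ma, eps$end_ma, areas)
}

#' @rdname read_range_table
#' @param matrices List of 0/1 matrices (from-area rows, to-area columns),
#'   oldest epoch first.
#' @param start_ma,end_ma Epoch bounds in Ma (start older than end).
#' @export
connectivity_model <- function(matrices, start_ma, end_ma, areas) {
  if (length(matrices) != length(start_ma)) stop("one matrix per epoch")
  if (any(start_ma <= end_ma)) stop("epoch start must be older than end")
  matrices <- lapply(matrices, function(m) {
    if (is.null(dimnames(m))) dimnames(m) <- list(areas, areas)
    m
  })
  ord <- order(start_ma, decreasing = TRUE)
  structure(
    list(matrices = matrices[ord],
         epochs = tibble::tibble(start_ma = start_ma[ord],
                                 end_ma = end_ma[ord]),
         areas = areas),
    class = "connectivity_model"
  )
}

#' @rdname read_range_table
#' @param cm A `connectivity_model`.
#' @export
write_connectivity <- function(cm, path) {
  blocks <- lapply(seq_along(cm$matrices), function(i) {
    data.frame(epoch = i, start_ma = cm$epochs$start_ma[i],
               end_ma = cm$epochs$end_ma[i], area = cm$areas,
               cm$matrices[[i]], check.names = FALSE)
  })
  df <- do.call(rbind, blocks)
  names(df)[-(1:4)] <- cm$areas
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Connectivity matrix in force at a given age (Ma); ages older than the
# oldest epoch use the oldest matrix, younger than the newest use the newest.
connectivity_at <- function(cm, age) {
  if (is.null(cm)) return(NULL)
  i <- findInterval(-age, -cm$epochs$start_ma)
  cm$matrices[[max(1L, min(length(cm$matrices), i))]]
}

#' Default area codes
#'
#' The 13 Old World areas used for muroid biogeography: South Western
#' Europe, Central Europe, Greece, Anatolia-Caucasus, West Central Asia,
#' Arabia, South Central Asia, East Central Asia, North Africa, East Africa,
#' South Africa, Russia, South East Asia.
#' @export
muroid_areas <- function() {
  c("SWE", "CE", "GR", "AC", "WCA", "AR", "SCA", "ECA", "NA",
    "EA", "SA", "RU", "SEA")
}
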