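#' Fire rotation period and annual percent area burned
#'
#' The fire rotation period (FRP) is the time needed to burn a cumulative
#' area equal to the area susceptible to burning: FRP = N * S / sum(A_y),
#' where N is the number of record years, S the susceptible area and A_y the
#' area burned in year y. The annual percentage of area burned is its
#' inverse, APAB = 100 / FRP. Computed for the whole landscape and per
#' land-cover class.
#'
#' @param x a [fire_history()] grid, or a data frame with columns `year`,
#'   `class`, `burned_ha` (one row per class-year).
#' @param ... passed to methods.
#' @return A data frame with one row per class plus an `"all"` row, columns
#'   `class`, `area_ha`, `years`, `burned_ha` (total burned over the record),
#'   `frp`, `apab`. Classes that never burned get `frp = Inf`, `apab = 0`.
#' @examples
#' # 100 ha landscape, 25 ha burned each of 12 years: FRP 4, APAB 25
#' tab <- data.frame(year = 1997:2008, class = "SS", burned_ha = 25)
#' fire_rotation(tab, areas = data.frame(class = "SS", area_ha = 100))
#' @export
fire_rotation <- function(x, ...) UseMethod("fire_rotation")

#' @rdname fire_rotation
#' @param exclude_classes land-cover labels excluded from the susceptible
#'   area (and from the overall figure).
#' @export
fire_rotation.fire_history <- function(x, exclude_classes = c("sand", "water"),
                                       ...) {
  ha_per_cell <- x$cell_size^2 / 1e4
  lc <- as.vector(x$land_cover)
  keep <- !(lc %in% exclude_classes) & !is.na(lc)
  nyears <- length(x$years)
  burns_flat <- matrix(x$burns, ncol = nyears)  # cell x year
  classes <- sort(unique(lc[keep]))
  rows <- lapply(classes, function(cl) {
    idx <- keep & lc == cl
    data.frame(class = cl, area_ha = sum(idx) * ha_per_cell,
               years = nyears,
               burned_ha = sum(burns_flat[idx, , drop = FALSE]) * ha_per_cell,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, data.frame(class = "all", area_ha = sum(tab$area_ha),
                               years = nyears,
                               burned_ha = sum(tab$burned_ha),
                               stringsAsFactors = FALSE))
  .finish_rotation(tab)
}

#' @rdname fire_rotation
#' @param areas data frame with columns `class`, `area_ha` giving each
#'   class's susceptible area.
#' @param years number of record years; defaults to the number of distinct
#'   years in `x`.
#' @export
fire_rotation.data.frame <- function(x, areas, years = NULL, ...) {
  need <- c("year", "class", "burned_ha")
  if (!all(need %in% names(x)))
    stop("'x' must have columns: ", paste(need, collapse = ", "))
  if (!all(c("class", "area_ha") %in% names(areas)))
    stop("'areas' must have columns 'class' and 'area_ha'")
  if (is.null(years)) years <- length(unique(x$year))
  stopifnot(years >= 1, all(areas$area_ha > 0))
  burned <- aggregate(list(burned_ha = x$burned_ha),
                      by = list(class = x$class), FUN = sum)
  tab <- merge(areas[c("class", "area_ha")], burned, by = "class",
               all.x = TRUE)
  tab$burned_ha[is.na(tab$burned_ha)] <- 0
  tab$years <- years
  tab <- tab[c("class", "area_ha", "years", "burned_ha")]
  tab <- rbind(tab, data.frame(class = "all", area_ha = sum(tab$area_ha),
                               years = years, burned_ha = sum(tab$burned_ha),
                               stringsAsFactors = FALSE))
  .finish_rotation(tab)
}

.finish_rotation <- function(tab) {
  tab$frp <- ifelse(tab$burned_ha > 0,
                    tab$years * tab$area_ha / tab$burned_ha, Inf)
  tab$apab <- 100 / tab$frp
  rownames(tab) <- NULL
  tab
}

#' Times-burned counts per grid cell
#'
#' Number of record years in which each cell burned — the basis of a
#' burned-times map and of the percent-of-area-burned-k-times breakdown.
#'
#' @param grid a [fire_history()] object.
#' @return An integer matrix with the grid's spatial dimensions.
#' @export
burn_count <- function(grid) {
  stopifnot(inherits(grid, "fire_history"))
  apply(grid$burns, c(1, 2), sum)
}
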