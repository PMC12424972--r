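#' Parcellation lookup
#'
#' A parcellation assigns every parcel an id and a large-scale network label,
#' and records how many parcels are cortical vs subcortical. The reference
#' atlas used at full scale is a 333-parcel cortical atlas plus 19 subcortical
#' regions (352 parcels total), but any sizes are accepted.
#'
#' @param parcel_ids character vector of unique parcel ids.
#' @param network_labels character vector, one network name per parcel.
#' @param n_cortical,n_subcortical integer split; must sum to the parcel count.
#' @return An object of class `parcellation` with fields `parcel_ids`,
#'   `network_labels`, `n_cortical`, `n_subcortical`.
#' @export
parcellation <- function(parcel_ids, network_labels,
                         n_cortical = length(parcel_ids), n_subcortical = 0L) {
  parcel_ids <- as.character(parcel_ids)
  network_labels <- as.character(network_labels)
  if (anyDuplicated(parcel_ids) > 0L) stop("parcel ids must be unique")
  if (length(parcel_ids) != length(network_labels))
    stop("need exactly one network label per parcel")
  if (length(parcel_ids) != n_cortical + n_subcortical)
    stop("n_cortical + n_subcortical must equal the parcel count")
  if (length(parcel_ids) < 2L) stop("a parcellation needs more than one parcel")
  structure(
    list(parcel_ids = parcel_ids, network_labels = network_labels,
         n_cortical = as.integer(n_cortical),
         n_subcortical = as.integer(n_subcortical)),
    class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d parcels (%d cortical + %d subcortical), %d networks\n",
              length(x$parcel_ids), x$n_cortical, x$n_subcortical,
              length(unique(x$network_labels))))
  invisible(x)
}

#' Number of parcels in a parcellation
#' @param parc a `parcellation`.
#' @return integer parcel count.
#' @export
n_parcels <- function(parc) length(parc$parcel_ids)

#' Build a parcellation from named network sizes
#'
#' Deterministically labels parcels `<network>_<k>` in the order the networks
#' are given. Used by the synthetic-cohort generator and convenient for tests.
#'
#' @param network_sizes named integer vector, parcels per network.
#' @param n_subcortical how many of the trailing parcels count as subcortical
#'   (bookkeeping only; does not affect any computation).
#' @return a `parcellation`.
#' @examples
#' make_parcellation(c(A = 3, B = 2))
#' @export
make_parcellation <- function(network_sizes, n_subcortical = 0L) {
  if (is.null(names(network_sizes)) || any(!nzchar(names(network_sizes))))
    stop("network_sizes must be a named vector")
  if (any(network_sizes <= 0)) stop("network sizes must be positive")
  labs <- rep(names(network_sizes), times = network_sizes)
  ids <- unlist(lapply(names(network_sizes), function(nw)
    paste0(nw, "_", seq_len(network_sizes[[nw]]))))
  P <- length(ids)
  parcellation(ids, labs, n_cortical = P - n_subcortical,
               n_subcortical = n_subcortical)
}

#' Read a parcel lookup table
#'
#' Expects a tab-separated table with columns `parcel_id`, `network` and
#' optionally `hemisphere`.
#'
#' @param path file path.
#' @param n_subcortical subcortical parcel count (default 0).
#' @return a `parcellation`.
#' @export
read_parcellation <- function(path, n_subcortical = 0L) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("parcel_id", "network") %in% names(tab)))
    stop("parcel lookup needs columns 'parcel_id' and 'network'")
  parcellation(tab$parcel_id, tab$network,
               n_cortical = nrow(tab) - n_subcortical,
               n_subcortical = n_subcortical)
}

#' Write a parcel lookup table
#' @param parc a `parcellation`.
#' @param path file path.
#' @export
write_parcellation <- function(parc, path) {
  utils::write.table(
    data.frame(parcel_id = parc$parcel_ids, network = parc$network_labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
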