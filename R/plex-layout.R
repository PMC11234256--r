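#' Construct a TMT plex layout
#'
#' A plex layout assigns every reporter channel of a multiplexed AP-MS run a
#' sample role -- wild-type bait (`"WT_BAIT"`), variant bait
#' (`"VARIANT_BAIT"`), no-transfection negative control
#' (`"NEGATIVE_CONTROL"`) -- and a biological replicate index.  Channels
#' with role `"UNUSED"` are carried in the layout but dropped by every
#' downstream stage.  Roles are always declared explicitly, never inferred
#' from channel names, because TMT channel naming is vendor-specific.
#'
#' @param channels Character vector of unique channel identifiers (for
#'   example `"TMT-126"`, `"TMT-127N"`).
#' @param roles Character vector, one role per channel, each one of
#'   `"WT_BAIT"`, `"VARIANT_BAIT"`, `"NEGATIVE_CONTROL"`, `"UNUSED"`.
#' @param replicates Positive integer replicate index per channel.  The
#'   (role, replicate) pair must be unique across channels (ignoring
#'   `"UNUSED"` channels).
#'
#' @return A `plex_layout`: a data frame with columns `channel`, `role`,
#'   `replicate`.
#' @seealso [read_layout()], [experimental_channels()]
#' @export
#' @examples
#' plex_layout(
#'   channels   = c("c1", "c2", "c3", "c4", "c5", "c6", "c7", "c8", "c9"),
#'   roles      = rep(c("WT_BAIT", "VARIANT_BAIT", "NEGATIVE_CONTROL"), each = 3),
#'   replicates = rep(1:3, times = 3)
#' )
plex_layout <- function(channels, roles, replicates) {
  .assert(length(channels) >= 1L, "apms_validation_error",
          "a plex layout needs at least one channel")
  .assert(length(roles) == length(channels) &&
            length(replicates) == length(channels),
          "apms_validation_error",
          "channels, roles and replicates must have equal length")
  channels <- as.character(channels)
  roles <- as.character(roles)
  .assert(!anyDuplicated(channels), "apms_validation_error",
          "channel identifiers must be unique")
  bad <- setdiff(unique(roles), .plex_roles)
  .assert(length(bad) == 0L, "apms_validation_error",
          "unknown channel role(s): %s", paste(bad, collapse = ", "))
  replicates <- as.integer(replicates)
  .assert(!anyNA(replicates) && all(replicates >= 1L),
          "apms_validation_error", "replicate indices must be positive integers")
  active <- roles != "UNUSED"
  key <- paste(roles[active], replicates[active])
  .assert(!anyDuplicated(key), "apms_validation_error",
          "duplicate (role, replicate) pair: %s",
          paste(unique(key[duplicated(key)]), collapse = ", "))
  structure(
    data.frame(channel = channels, role = roles, replicate = replicates,
               stringsAsFactors = FALSE),
    class = c("plex_layout", "data.frame")
  )
}

#' Read a plex layout from a JSON config file
#'
#' The expected format is
#' `{"channels": [{"id": "TMT-126", "role": "WT_BAIT", "replicate": 1}, ...]}`.
#'
#' @param path Path to the JSON layout file.
#' @return A [plex_layout()].
#' @export
read_layout <- function(path) {
  .assert(file.exists(path), "apms_io_error", "layout file not found: %s", path)
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  .assert(is.list(cfg) && !is.null(cfg$channels), "apms_validation_error",
          "layout JSON must contain a 'channels' array")
  ch <- cfg$channels
  .assert(is.data.frame(ch) && nrow(ch) >= 1L, "apms_validation_error",
          "layout 'channels' array must be non-empty")
  .assert(all(c("id", "role", "replicate") %in% names(ch)),
          "apms_validation_error",
          "each layout channel needs fields id, role and replicate")
  plex_layout(ch$id, ch$role, ch$replicate)
}

#' Write a plex layout to a JSON config file
#'
#' @param layout A [plex_layout()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plex_layout"))
  obj <- list(channels = data.frame(id = layout$channel, role = layout$role,
                                    replicate = layout$replicate))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Channels of a layout by role
#'
#' `channels_for_role()` returns the channel identifiers carrying a given
#' role, ordered by replicate index.  `experimental_channels()` returns the
#' bait-expressing channels (wild-type followed by variant);
#' `control_channels()` the negative-control channels.
#'
#' @param layout A [plex_layout()].
#' @param role One of `"WT_BAIT"`, `"VARIANT_BAIT"`, `"NEGATIVE_CONTROL"`,
#'   `"UNUSED"`.
#' @return Character vector of channel identifiers.
#' @export
channels_for_role <- function(layout, role) {
  stopifnot(inherits(layout, "plex_layout"))
  role <- match.arg(role, .plex_roles)
  sel <- layout[layout$role == role, , drop = FALSE]
  sel$channel[order(sel$replicate)]
}

#' @rdname channels_for_role
#' @export
experimental_channels <- function(layout) {
  c(channels_for_role(layout, "WT_BAIT"),
    channels_for_role(layout, "VARIANT_BAIT"))
}

#' @rdname channels_for_role
#' @export
control_channels <- function(layout) {
  channels_for_role(layout, "NEGATIVE_CONTROL")
}

# Active (non-UNUSED) channels in layout order.
.active_channels <- function(layout) {
  layout$channel[layout$role != "UNUSED"]
}

# A layout usable for the full comparative pipeline: at least two replicate
# channels in each of the three sample roles.
.check_runnable <- function(layout) {
  for (role in c("WT_BAIT", "VARIANT_BAIT", "NEGATIVE_CONTROL")) {
    .assert(length(channels_for_role(layout, role)) >= 2L,
            "apms_config_error",
            "layout needs at least 2 channels with role %s", role)
  }
  invisible(TRUE)
}
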