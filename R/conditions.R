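#' The 10-condition affordance-by-ego-motion design
#'
#' Returns the fixed factorial mapping between condition ids and the three
#' stimulus factors: navigational affordance (side of the open doorway),
#' ego-motion direction, and affordance/ego-motion consistency. Conditions
#' 1-6 depict translation (forward or backward) through rooms with a doorway
#' on the left, the right, or both sides; conditions 7-10 depict turns, which
#' are "consistent" when the turn is toward the open doorway and
#' "inconsistent" when it is toward the painting.
#'
#' @return A tibble with 10 rows and columns `condition_id` (integer 1-10),
#'   `affordance` (`"left"`, `"right"`, `"both"`), `ego_motion` (`"forward"`,
#'   `"backward"`, `"left_turn"`, `"right_turn"`), and `consistency`
#'   (`"consistent"`, `"inconsistent"`, `"not_applicable"`).
#' @examples
#' condition_table()
#' @export
condition_table <- function() {
  ct <- .cond_cache$table
  if (is.null(ct)) {
    ct <- tibble::tibble(
      condition_id = 1:10,
      affordance = c("both", "left", "right", "both", "left", "right",
                     "left", "right", "left", "right"),
      ego_motion = c(rep("forward", 3), rep("backward", 3),
                     rep("left_turn", 2), rep("right_turn", 2)),
      consistency = c(rep("not_applicable", 6), "consistent", "inconsistent",
                      "inconsistent", "consistent")
    )
    .cond_cache$table <- ct
  }
  ct
}

.cond_cache <- new.env(parent = emptyenv())

# Condition-id groups used throughout; derived once from the table so every
# module shares a single source of truth.
cond_groups <- function() {
  g <- .cond_cache$groups
  if (!is.null(g)) return(g)
  ct <- condition_table()
  g <- list(
    forward     = ct$condition_id[ct$ego_motion == "forward"],
    backward    = ct$condition_id[ct$ego_motion == "backward"],
    left_turn   = ct$condition_id[ct$ego_motion == "left_turn"],
    right_turn  = ct$condition_id[ct$ego_motion == "right_turn"],
    turns       = ct$condition_id[ct$ego_motion %in% c("left_turn", "right_turn")],
    door_left   = ct$condition_id[ct$affordance == "left"],
    door_right  = ct$condition_id[ct$affordance == "right"],
    door_both   = ct$condition_id[ct$affordance == "both"],
    consistent   = ct$condition_id[ct$consistency == "consistent"],
    inconsistent = ct$condition_id[ct$consistency == "inconsistent"]
  )
  .cond_cache$groups <- g
  g
}

#' @keywords internal
rois_default <- function() c("OPA", "PPA", "MPA", "EVC")
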