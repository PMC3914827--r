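# Stage-game payoff tables. u1[i][j] is player 1's payoff when player 1 picks
# action i-1 and player 2 picks action j-1 (actions are coded 0/1; rows are
# player 1's action, columns player 2's action). All payoff values used by the
# package live here; code never hard-codes them.
#
# hide_and_seek: symmetric zero-sum competition. Player 1 is the seeker and
# wins (+1) when actions match; player 2 (the hider) wins when they differ.
#
# battle_of_the_sexes: unbalanced coordination. Matching is strictly better
# than mismatching for both players, but each player prefers a different
# matching cell (player 1 prefers matching on action 0, player 2 on action 1).
hide_and_seek:
  u1:
    - [1, -1]
    - [-1, 1]
  u2:
    - [-1, 1]
    - [1, -1]
battle_of_the_sexes:
  u1:
    - [2, 0]
    - [0, 1]
  u2:
    - [1, 0]
    - [0, 2]
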