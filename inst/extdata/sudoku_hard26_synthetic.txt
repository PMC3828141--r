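# Synthetic stand-in puzzle: hard-rated 9x9 Sudoku with 26 givens and a
# unique solution, generated programmatically (uniqueness verified by
# exhaustive backtracking).  "Hard" operationally: iterated naked/hidden
# singles do not solve it (15 cells remain open after full singles
# propagation).
# Line 1: puzzle (row-major, 0 = blank).  Line 2: unique solution.
430060000200075006600000017063000970040000000000387040510000000004920000000041000
437162589291875436685493217163254978748619352952387641519736824374928165826541793
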