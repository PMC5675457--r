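# Glucose predictor grammar.
# A predictor combines three signal blocks (lagged CGM, meal rate of
# appearance, insulin on board) and an optional circadian sinusoid.
# Each GetX term reads one lagged sample of its source signal on the 5-min
# CGM grid, divides it by a scale constant, applies a chain of unary
# pre-operators, and offsets the result with a constant; the terms of a
# block are summed.  Lags are in CGM samples (1 sample = 5 min); the two
# lag arguments give the start and end of the admissible lag window and
# must satisfy start < end.  Constants are fixed-point in [00.0, 99.9].
[Body] ::= ExprG=([G][op][Ra][op][IOB])[op][Circadian]
[G] ::= GetG([PrevIni],[PrevFin],[op],[preop],[Cte],[Cte])[G] | λ
[Ra] ::= GetRa([PrevIni],[PrevFin],[op],[preop],[Cte],[Cte])[Ra] | λ
[IOB] ::= GetIOB([PrevIni],[PrevFin],[op],[preop],[Cte],[Cte])[IOB] | λ
[preop] ::= sqrt | sin | log | pow | exp | cos | [preop][preop] | λ
[Circadian] ::= GetCircadian([OpB],[Cte],[Cte],[Cte]) | λ
[Cte] ::= ([Dgt][Dgt].[Dgt])
[op] ::= [OpA] | [OpB]
[PrevIni] ::= 0 | 1 | 2 | 4 | 6 | 8 | 10 | 12 | 14 | 16 | 18 | 20 | 22
[PrevFin] ::= 1 | 2 | 4 | 6 | 8 | 10 | 12 | 14 | 16 | 18 | 20 | 22 | 24
[Dgt] ::= 0 | 1 | 2 | 3 | 4 | 5 | 6 | 7 | 8 | 9
[OpA] ::= + | -
[OpB] ::= / | *
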