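# Participant roster of the Löwenmensch cross-domain-transfer study.
# Transcribed from the study's demographic table: nine artists, of whom
# three (AS, LN, ND) form the musical group SLT; experience is a lower
# bound in years ("> 15" recorded as 15).  provided_description marks the
# records for which a creative-process description was returned (the two
# individuals SW and WC, and the group SLT).
code	medium	age	nationality	experience_min_years	group_members	provided_description
SLT	Music (group)	-	-	-	AS;LN;ND	TRUE
AS	Music - Percussion	33	USA	15	-	FALSE
LN	Music - Vocals	36	Canada	20	-	FALSE
ND	Music - Cello / Computer	27	Persia/Russia	10	-	FALSE
SW	Written word (Novelist)	71	Australia	30	-	TRUE
WC	Music	67	Australia	30	-	TRUE
MG	Music	38	USA	20	-	FALSE
LH	Written word (Poetry)	78	Australia	30	-	FALSE
SD	Visual Art	64	Canada/USA	30	-	FALSE
SB	Written word (Novelist and Playwright)	67	USA	30	-	FALSE
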