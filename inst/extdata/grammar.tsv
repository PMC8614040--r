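# Gleason score extraction grammar, version 1.
# Ordered PCRE rules applied to normalized (lowercased, spelling-mapped)
# report text. Columns: rule_id, roles (space-separated role of each capture
# group: major | minor | total), pattern, description.
# Overlapping matches are resolved longest-first, then earliest-start, then
# by the order of the rules in this file.
rule_id	roles	pattern	description
paren_major_minor	major minor total	(?<![0-9.])([0-9])\s*\(\s*major\s*\)\s*(?:\+|plus)\s*([0-9])\s*\(\s*minor\s*\)(?:\s*(?:=|equals)\s*([0-9]{1,2})(?:\s*/\s*10)?)?	M (MAJOR) + m (MINOR) = T/10
score_total_components	total major minor	score\s*:?\s*(?:of\s+)?([0-9]{1,2})\s*\(\s*major\s*:?\s*([0-9])\s*[;,]?\s*minor\s*:?\s*([0-9])\s*\)	SCORE T (MAJOR M; MINOR m)
major_minor_keywords	major minor total	major\s*(?:pattern)?\s*:?\s*(?:is\s+)?([0-9])(?:\s*/\s*5)?\s*(?:[,;]|\+|plus)?\s*minor\s*(?:pattern)?\s*:?\s*(?:is\s+)?([0-9])(?:\s*/\s*5)?(?:\s*(?:=|equals)\s*([0-9]{1,2})(?:\s*/\s*10)?)?	MAJOR [PATTERN] M [, + plus] MINOR [PATTERN] m [= T], denominators /5 stripped
total_with_component_parens	total major minor	(?<![0-9.])([0-9]{1,2})\s*\(\s*([0-9])\s*(?:\+|plus)\s*([0-9])\s*\)	T (M + m)
pair_equals_total	major minor total	(?<![0-9.])\(?\s*([0-9])\s*(?:\+|plus)\s*([0-9])\s*\)?\s*(?:=|equals)\s*([0-9]{1,2})(?!\.?[0-9])(?:\s*/\s*10)?	M + m = T, (M + m) = T, M plus m equals T
keyword_digit_pair	major minor	gleason\s*:?\s*(?:(?:score|grade)s?\s*:?\s*)?(?:of\s+)?([0-9])\s*[,;]\s*([0-9])(?!\.?[0-9])	GLEASON M, m and GLEASON M;m (pair only valid adjacent to the keyword)
bare_pair	major minor	(?<![0-9.])([0-9])\s*(?:\+|plus)\s*([0-9])(?!\.?[0-9])	M + m
keyword_total_only	total	gleason\s*:?\s*(?:(?:score|grade)s?\s*:?\s*)?(?:of\s+)?(?:is\s+)?([0-9]{1,2})(?!\.?[0-9])(?!\s*(?:[,;+/=(]|plus|equals))	GLEASON [SCORE] T with no components stated
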