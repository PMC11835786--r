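# Per-nutrient daily intake reference ranges used to classify estimated
# FFQ intake as Low (< lower), Normal (inside, bounds inclusive) or
# High (> upper).
#
# These defaults are population dietary-reference-value style placeholders
# for a generic adult and are NOT clinical thresholds; edit this file to
# match the population under study. Units per day: fiber, fats, protein
# and carbohydrate in g; calcium and iron in mg; vitamin C in mg;
# vitamin A in ug RE; vitamin B12 in ug.
fiber:               {lower: 25,   upper: 40}
vitamin_a:           {lower: 600,  upper: 3000}
vitamin_b12:         {lower: 2.4,  upper: 100}
vitamin_c:           {lower: 75,   upper: 1000}
monounsaturated_fat: {lower: 20,   upper: 45}
polyunsaturated_fat: {lower: 10,   upper: 25}
protein:             {lower: 50,   upper: 120}
total_fat:           {lower: 50,   upper: 95}
calcium:             {lower: 950,  upper: 2500}
iron:                {lower: 11,   upper: 45}
saturated_fat:       {lower: 0,    upper: 24}
carbohydrate:        {lower: 130,  upper: 330}
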