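# Explanation sentence templates, English locale. "{pct}" is replaced by
# the configured hybrid component weight rendered as an integer percent,
# "{frac}" by the neighbour order fraction as an integer percent.
nutritional_headline: "Your recommendations are {pct}% influenced by your nutritional profile."
past_headline: "Based on your previously chosen meals, we try to find similar recipes."
past_fallback: "You have no order history yet, so your recommendations are driven by your nutritional profile."
popularity_headline: "The most popular meals are not always the healthiest meals. Therefore, the popularity of a meal is only taken into account for {pct}%."
popularity_detail: "{frac}% of users with similar dietary patterns ordered this meal."
popularity_inactive: "Meal popularity is not yet taken into account: the system is still collecting order data."
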