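# Heart-protective diet score taxonomy: 22 signed food groups built from
# Oxford WebQ 24 h recall items. direction +1 = heart-protective (higher
# intake scores higher), -1 = discouraged (higher intake scores lower).
# serve_size_g is grams (drinks: mL treated 1:1 as grams) per standard serve.
# Item identifiers are slugified from the item names at load time.
name: heart_protective_diet_22
groups:
  - group_id: wholegrains
    name: Wholegrains
    direction: 1
    serve_size_g: 60
    items:
      - Porridge
      - Muesli
      - Oat crunch
      - Bran cereal
      - Non-white bread (brown, wholemeal, or other flour)
      - Seeded or other bread
      - Crispbread
      - Whole-wheat cereal
      - Other cereal
      - Oatcakes
      - Wholemeal pasta
      - Brown rice
      - Couscous
      - Other cooked grains (such as bulgur)
  - group_id: fruits
    name: Fruits
    direction: 1
    serve_size_g: 80
    items:
      - Avocado
      - Mixed fruit
      - Apple
      - Banana
      - Berries
      - Cherries
      - Grapefruit
      - Grapes
      - Mango
      - Melon
      - Orange
      - Orange-like small fruits (such as satsuma)
      - Peach/nectarine
      - Pear
      - Pineapple
      - Plum
      - Other fruits
      - Stewed/cooked fruit
      - Prunes
      - Other dried fruit
  - group_id: nonstarchy_vegetables
    name: Non-starchy Vegetables
    direction: 1
    serve_size_g: 80
    items:
      - Mixed vegetables
      - Vegetable pieces
      - Coleslaw
      - Side salad
      - Beetroot
      - Broccoli
      - Cabbage/kale
      - Carrots
      - Cauliflower
      - Celery
      - Courgette
      - Cucumber
      - Garlic
      - Leeks
      - Lettuce
      - Mushrooms
      - Onion
      - Parsnip
      - Sweet peppers
      - Spinach
      - Sprouts
      - Fresh tomatoes
      - Cooked or tinned tomatoes
      - Turnip/swede
      - Watercress
      - Other vegetable intake
  - group_id: starchy_vegetables
    name: Starchy Vegetables
    direction: 1
    serve_size_g: 75
    items:
      - Butternut squash
      - Sweetcorn
      - Sweet potato
  - group_id: nuts_seeds
    name: Nuts and Seeds
    direction: 1
    serve_size_g: 30
    items:
      - Unsalted peanuts
      - Unsalted nuts
      - Sunflower seeds
      - Pumpkin seeds
      - Other seeds
  - group_id: legumes_beans
    name: Legumes and Beans, Other Vegetarian Protein Alternatives
    direction: 1
    serve_size_g: 80
    items:
      - Beans
      - Other beans
      - Lentils
      - Other pulses
      - Broad beans
      - Green beans
      - Peas
      - Tofu
      - Quorn
  - group_id: uncoated_fish_seafood
    name: Uncoated Fish and Seafood
    direction: 1
    serve_size_g: 140
    items:
      - Tinned tuna
      - Oily fish
      - White fish
      - Prawns
      - Lobster/crab
      - Shellfish
      - Other fish intake
  - group_id: eggs
    name: Eggs
    direction: 1
    serve_size_g: 120
    items:
      - Whole eggs
      - Omelettes or scrambled eggs
      - Eggs in sandwiches
      - Scotch egg
      - Other egg dishes
  - group_id: reduced_fat_dairy
    name: (Reduced-fat and/or No Added Sugar) Milk and Dairy Products
    direction: 1
    serve_size_g: 250
    items:
      - Milk
      - Low fat hard cheese
      - Low fat cheese spread
      - Cottage cheese
  - group_id: tea_coffee_lowcal_drinks
    name: Tea, Coffee and Other Low-calorie Drinks
    direction: 1
    serve_size_g: 250
    items:
      - Instant coffee
      - Filtered coffee
      - Cappuccino
      - Latte
      - Espresso
      - Other coffee drinks
      - Standard tea
      - Rooibos tea
      - Green tea
      - Herbal tea
      - Other tea
  - group_id: homemade_soup
    name: Homemade soup
    direction: 1
    serve_size_g: 250
    items:
      - Homemade soup
  - group_id: refined_grains
    name: Refined grains and cereals, including discretionary choices
    direction: -1
    serve_size_g: 60
    items:
      - Sweetened cereal
      - Plain cereal
      - White sliced bread
      - White bread
      - White bap
      - White bread roll
      - Naan bread
      - Garlic bread
      - White pasta
      - White rice
      - Pancake
      - Snackpot
  - group_id: potatoes
    name: Potatoes
    direction: -1
    serve_size_g: 75
    items:
      - Fried potatoes
      - Boiled/baked potatoes
      - Mashed potatoes
      - Crisps
  - group_id: meat_poultry_processed
    name: Meat, Poultry, and Processed Meat
    direction: -1
    serve_size_g: 70
    items:
      - Sausage
      - Beef
      - Pork
      - Lamb
      - Crumbed or deep-fried poultry
      - Poultry
      - Bacon
      - Ham
      - Liver
      - Other meat intake
  - group_id: coated_fish_seafood
    name: Coated Fish and Seafood
    direction: -1
    serve_size_g: 140
    items:
      - Breaded fish
      - Battered fish
  - group_id: full_fat_dairy
    name: (Full-fat and/or Added Sugar) Milk and Dairy Products
    direction: -1
    serve_size_g: 250
    items:
      - Flavored milk
      - Yogurt
      - Hard cheese
      - Soft cheese
      - Blue cheese
      - Cheese spread
      - Feta cheese
      - Mozzarella cheese
      - Goat's cheese
      - Other cheese
  - group_id: processed_soup
    name: Processed Soup
    direction: -1
    serve_size_g: 250
    items:
      - Powdered/instant soup intake
      - Canned soup intake
  - group_id: sweets_desserts
    name: Sugar, Sweets and Desserts, Cookies, and Pastries
    direction: -1
    serve_size_g: 40
    items:
      - Sugar added to coffee/tea/cereal
      - Ice-cream
      - Milk-based pudding
      - Other milk-based pudding
      - Soya dessert
      - Fruitcake
      - Cake
      - Doughnuts
      - Sponge pudding
      - Cheesecake
      - Other dessert
      - Chocolate bar
      - White chocolate
      - Milk chocolate
      - Dark chocolate
      - Chocolate-covered raisin
      - Chocolate sweet
      - Diet sweets
      - Chocolate-covered biscuits
      - Chocolate biscuits
      - Sweet biscuits
      - Cereal bar
      - Other sweets
  - group_id: savory_snacks
    name: Savory Snacks
    direction: -1
    serve_size_g: 30
    items:
      - Savory or cheesy biscuits
      - Other savory snacks
  - group_id: sugary_drinks
    name: Sugary Drinks including Juices and Sugar-sweetened Beverages
    direction: -1
    serve_size_g: 150
    items:
      - Low-calorie hot chocolate
      - Hot chocolate
      - Other non-alcoholic drinks
  - group_id: artificial_sweetener
    name: Artificial sweetener
    direction: -1
    serve_size_g: 4
    items:
      - Artificial sweetener added to coffee/tea/cereal
  - group_id: unhealthy_fat
    name: Unhealthy Fat (with/without Carbohydrates)
    direction: -1
    serve_size_g: 10
    items:
      - Butter/margarine on bread/crackers
      - Bread slices with butter/margarine
# Items recorded by the recall instrument but deliberately excluded from the
# score: alcoholic beverages, highly processed vegetarian meat alternatives,
# vegetable fats, and salted nuts.
ignore_items:
  - red_wine
  - white_wine
  - beer_cider
  - spirits
  - fortified_wine
  - other_alcoholic_drinks
  - vegetarian_sausage
  - vegetarian_burger
  - other_vegetarian_alternative
  - vegetable_fat_spread
  - cooking_oil
  - salted_peanuts
  - salted_nuts
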